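trial_log_columns <- c("subject_id", "task_variant", "session", "trial_index",
                       "choice", "outcome", "pellets", "penalty_s",
                       "cue_played", "premature", "omission",
                       "latency_choice_s", "latency_collect_s")

#' Validate a trial-log tibble against the canonical schema
#'
#' Checks the column set, key uniqueness of (subject, session, trial), and
#' outcome-field consistency: wins must carry pellets and no penalty,
#' losses a penalty and no pellets, premature/omission rows neither. Every
#' violation is reported with its row number.
#'
#' @param trials Tibble to validate.
#' @return The validated tibble (invisibly unchanged); errors list every
#'   offending row otherwise.
#' @export
validate_trial_log <- function(trials) {
  missing <- setdiff(trial_log_columns, names(trials))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  key <- paste(trials$subject_id, trials$session, trials$trial_index)
  if (anyDuplicated(key))
    stop("duplicate (subject, session, trial_index) keys at row(s): ",
         paste(head(which(duplicated(key)), 5), collapse = ", "), call. = FALSE)
  bad_outcome <- !trials$outcome %in% c("win", "loss", "premature", "omission")
  bad_win <- trials$outcome == "win" & (trials$pellets <= 0 | trials$penalty_s != 0)
  bad_loss <- trials$outcome == "loss" & (trials$pellets != 0 | trials$penalty_s <= 0)
  inval <- trials$outcome %in% c("premature", "omission") &
    (!is.na(trials$choice) | trials$pellets != 0 | trials$penalty_s != 0)
  bad_flags <- (trials$premature != as.integer(trials$outcome == "premature")) |
    (trials$omission != as.integer(trials$outcome == "omission"))
  problems <- which(bad_outcome | bad_win | bad_loss | inval | bad_flags)
  if (length(problems))
    stop("inconsistent outcome fields at row(s): ",
         paste(head(problems, 10), collapse = ", "), call. = FALSE)
  invisible(trials)
}

#' Write a trial log to CSV
#'
#' @param trials Validated trial-log tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  validate_trial_log(trials)
  out <- trials[, trial_log_columns]
  out$cue_played <- as.integer(out$cue_played)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read and validate a trial log
#'
#' Parses the canonical CSV, validates it (see [validate_trial_log()]),
#' and flags rows usable for modeling (valid win/loss choices); premature
#' and omission rows are retained but marked `valid_for_modeling = FALSE`.
#'
#' @param path CSV path.
#' @return Validated tibble with a `valid_for_modeling` column appended.
#' @export
read_trial_log <- function(path) {
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      task_variant = readr::col_character(),
      session = readr::col_integer(),
      trial_index = readr::col_integer(),
      choice = readr::col_character(),
      outcome = readr::col_character(),
      pellets = readr::col_integer(),
      penalty_s = readr::col_double(),
      cue_played = readr::col_integer(),
      premature = readr::col_integer(),
      omission = readr::col_integer(),
      latency_choice_s = readr::col_double(),
      latency_collect_s = readr::col_double()
    ))
  trials$cue_played <- trials$cue_played == 1L
  validate_trial_log(trials)
  dplyr::mutate(trials, valid_for_modeling = .data$outcome %in% c("win", "loss"))
}

#' Exclude subjects with incomplete early training
#'
#' Subjects missing any of sessions `1..required_sessions` cannot enter the
#' learning-phase model fits and are dropped, with a per-subject report of
#' which sessions were missing.
#'
#' @param trials Validated trial-log tibble.
#' @param required_sessions Number of consecutive initial sessions required.
#' @return A list: `retained` (tibble of kept trials) and `excluded`
#'   (tibble `subject_id`, `reason`).
#' @export
exclude_incomplete_subjects <- function(trials, required_sessions = 5) {
  need <- seq_len(required_sessions)
  report <- trials |>
    dplyr::distinct(.data$subject_id, .data$session) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(missing = list(setdiff(need, .data$session)),
                     .groups = "drop") |>
    dplyr::mutate(n_missing = purrr::map_int(.data$missing, length))
  excluded <- report |>
    dplyr::filter(.data$n_missing > 0) |>
    dplyr::mutate(reason = purrr::map_chr(
      .data$missing,
      function(m) paste("missing session", paste(m, collapse = ", ")))) |>
    dplyr::select("subject_id", "reason")
  list(retained = dplyr::filter(trials, !.data$subject_id %in% excluded$subject_id),
       excluded = excluded)
}
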