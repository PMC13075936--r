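choice_percentages_vec <- function(choice) {
  counts <- table(factor(choice, levels = paste0("P", 1:4)))
  if (sum(counts) == 0) stop("no valid choices", call. = FALSE)
  setNames(100 * as.numeric(counts) / sum(counts), paste0("P", 1:4))
}

#' Percent choice of each option
#'
#' `100 * times chosen / total valid choices` per option; premature
#' responses and omissions are excluded from the denominator.
#'
#' @param trials Trial-log tibble for one subject.
#' @param sessions Optional session window to restrict to.
#' @return Named numeric 4-vector (`P1`..`P4`) summing to 100.
#' @export
choice_percentages <- function(trials, sessions = NULL) {
  if (!is.null(sessions)) trials <- dplyr::filter(trials, .data$session %in% sessions)
  trials <- dplyr::filter(trials, .data$outcome %in% c("win", "loss"))
  setNames(choice_percentages_vec(trials$choice), paste0("P", 1:4))
}

#' Decision score
#'
#' `(P1% + P2%) - (P3% + P4%)`: positive scores indicate preference for
#' the long-run optimal options, negative scores risk preference.
#'
#' @param pct Percent-choice 4-vector summing to 100.
#' @return Score in \[-100, 100\].
#' @export
decision_score <- function(pct) {
  if (length(pct) != 4 || abs(sum(pct) - 100) > 1e-6)
    stop("pct must be a 4-vector summing to 100", call. = FALSE)
  (pct[[1]] + pct[[2]]) - (pct[[3]] + pct[[4]])
}

#' Risk-status classification
#'
#' Positive decision scores are classified `"optimal"`, negative scores
#' `"risk_preferring"`. A score of exactly zero (a measure-zero boundary in
#' continuous data) is classified optimal by convention.
#'
#' @param score Decision score in \[-100, 100\].
#' @return `"optimal"` or `"risk_preferring"` (vectorised).
#' @export
classify_risk_status <- function(score) {
  stopifnot(all(score >= -100 & score <= 100))
  ifelse(score >= 0, "optimal", "risk_preferring")
}

#' Premature-response rate
#'
#' `100 * premature responses / trials initiated`, where initiated trials
#' include premature, omitted and valid trials.
#'
#' @param trials Trial-log tibble.
#' @return Percentage in \[0, 100\].
#' @export
premature_rate <- function(trials) {
  if (!nrow(trials)) stop("no initiated trials", call. = FALSE)
  100 * sum(trials$outcome == "premature") / nrow(trials)
}

#' Arcsine transform of a percentage
#'
#' `asin(sqrt(p / 100))`, the variance-stabilising transform used to limit
#' the influence of the 0/100% ceiling on percentage endpoints.
#'
#' @param percent Value(s) in \[0, 100\].
#' @return Radians in \[0, pi/2\].
#' @export
arcsine_transform <- function(percent) {
  if (any(percent < 0 | percent > 100)) stop("percent must lie in [0, 100]",
                                             call. = FALSE)
  asin(sqrt(percent / 100))
}

#' Latest statistically stable session window
#'
#' Scans k-session windows from the latest backwards and returns the first
#' whose session effect is non-significant in a randomized-block ANOVA
#' (score ~ session + subject) at level `alpha` — the baseline window over
#' which endpoint measures are averaged. If no window is stable the last k
#' sessions are returned with a warning.
#'
#' @param scores Tibble with columns `subject_id`, `session`, `score`
#'   (one row per subject x session).
#' @param k Window length in sessions (default 4).
#' @param alpha Significance level of the stability test.
#' @return Integer vector of the k session numbers in the chosen window.
#' @export
stable_window <- function(scores, k = 4, alpha = 0.05) {
  sess <- sort(unique(scores$session))
  if (length(sess) < k) stop("fewer than k sessions available", call. = FALSE)
  windows <- rev(seq_len(length(sess) - k + 1))
  for (i in windows) {
    win <- sess[i:(i + k - 1)]
    d <- dplyr::filter(scores, .data$session %in% win)
    if (session_effect_p(d) >= alpha) return(win)
  }
  warning("no stable window found; returning the last k sessions", call. = FALSE)
  tail(sess, k)
}

session_effect_p <- function(d) {
  if (length(unique(d$subject_id)) < 2)
    stop("stability test needs >= 2 subjects", call. = FALSE)
  tab <- anova(lm(score ~ factor(subject_id) + factor(session), data = d))
  ss <- tab["factor(session)", "Sum Sq"]
  if (!is.finite(ss) || ss < 1e-12) return(1)  # flat in session: stable
  p <- tab["factor(session)", "Pr(>F)"]
  if (!is.finite(p)) 1 else p
}

#' Per-subject behavioral summary over a session window
#'
#' The study's endpoint measures for each subject: percent choice of each
#' option, decision score, risk status, premature-response rate, trials
#' completed, omissions, and mean latencies.
#'
#' @param trials Trial-log tibble (any number of subjects).
#' @param sessions Optional session window.
#' @return Tibble keyed by `subject_id` (and `task_variant` if present).
#' @export
behavior_summary <- function(trials, sessions = NULL) {
  if (!is.null(sessions)) trials <- dplyr::filter(trials, .data$session %in% sessions)
  keys <- intersect(c("subject_id", "task_variant"), names(trials))
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, g) {
      pct <- choice_percentages(d)
      score <- decision_score(pct)
      tibble::tibble(
        pct_P1 = pct[[1]], pct_P2 = pct[[2]], pct_P3 = pct[[3]], pct_P4 = pct[[4]],
        decision_score = score,
        risk_status = classify_risk_status(score),
        premature_pct = premature_rate(d),
        trials_completed = sum(d$outcome %in% c("win", "loss")),
        omissions = sum(d$outcome == "omission"),
        latency_choice_s = mean(d$latency_choice_s, na.rm = TRUE),
        latency_collect_s = mean(d$latency_collect_s, na.rm = TRUE)
      )
    }) |>
    dplyr::ungroup()
}

#' Choice shift after reinforcer devaluation
#'
#' Per-option difference in percent choice, devaluation minus baseline
#' (so the deltas sum to zero), plus the decision-score shift.
#'
#' @param baseline,devalued One-row [behavior_summary()] tibbles for the
#'   same subject.
#' @return One-row tibble: `subject_id`, `delta_P1..delta_P4`,
#'   `delta_decision_score`.
#' @export
devaluation_shift <- function(baseline, devalued) {
  if (!identical(baseline$subject_id, devalued$subject_id))
    stop("baseline and devaluation summaries must come from the same subject",
         call. = FALSE)
  cols <- paste0("pct_P", 1:4)
  d <- as.numeric(devalued[1, cols]) - as.numeric(baseline[1, cols])
  tibble::tibble(subject_id = baseline$subject_id,
                 delta_P1 = d[1], delta_P2 = d[2], delta_P3 = d[3],
                 delta_P4 = d[4],
                 delta_decision_score =
                   devalued$decision_score - baseline$decision_score)
}

#' One-way ANOVA of a score across groups
#'
#' Between-groups F-test (classical between/within mean-square ratio) of,
#' e.g., decision score across task variants.
#'
#' @param score Numeric response vector.
#' @param group Group labels, same length.
#' @return One-row tibble: `f_stat`, `df_between`, `df_within`, `p_value`.
#' @export
one_way_anova <- function(score, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(group) < 2)) stop("each group needs >= 2 values", call. = FALSE)
  tab <- anova(lm(score ~ group))
  tibble::tibble(f_stat = tab$`F value`[1],
                 df_between = tab$Df[1], df_within = tab$Df[2],
                 p_value = tab$`Pr(>F)`[1])
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise group mean differences with familywise-adjusted p-values
#' from the studentized-range distribution (Tukey-Kramer standard errors
#' for unequal group sizes). Differences are reported row-minus-column:
#' `group1` mean minus `group2` mean, with `group1` the earlier factor
#' level.
#'
#' @inheritParams one_way_anova
#' @return Tibble: `group1`, `group2`, `mean_diff`, `p_adj`.
#' @export
tukey_hsd <- function(score, group) {
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(group) < 2)) stop("each group needs >= 2 values", call. = FALSE)
  n <- length(score)
  means <- tapply(score, group, mean)
  ns <- tapply(score, group, length)
  mse <- sum(tapply(score, group, function(x) sum((x - mean(x))^2))) / (n - k)
  pairs <- utils::combn(levels(group), 2)
  purrr::map(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    diff <- means[[g1]] - means[[g2]]
    se <- sqrt(mse / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    q <- if (se == 0) { if (abs(diff) < 1e-12) 0 else Inf } else abs(diff) / se
    tibble::tibble(group1 = g1, group2 = g2, mean_diff = diff,
                   p_adj = ptukey(q, k, n - k, lower.tail = FALSE))
  }) |> dplyr::bind_rows()
}
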