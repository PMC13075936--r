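#' Reinforcement schedule of the rat gambling task
#'
#' The rGT offers four response options that trade per-trial reward size
#' against the probability and duration of a time-out penalty. P1 and P2 are
#' long-run optimal (small, likely rewards and short, rare penalties); P3 and
#' P4 are risky (large rewards but long, frequent penalties that suppress the
#' number of trials a session can hold). The default schedule is the canonical
#' one: P2 maximises pellets earned per 30-minute session.
#'
#' @param reward_pellets Integer pellets delivered on a win, one per option.
#' @param p_win Win probability per option.
#' @param penalty_s Time-out penalty duration (seconds) per option.
#'
#' @return A tibble with one row per option and columns `option`,
#'   `reward_pellets`, `p_win`, `penalty_s`, `p_penalty` (always
#'   `1 - p_win`: every trial is either rewarded or punished).
#' @examples
#' rgt_schedule()
#' @export
rgt_schedule <- function(reward_pellets = c(1L, 2L, 3L, 4L),
                         p_win = c(0.9, 0.8, 0.5, 0.4),
                         penalty_s = c(5, 10, 30, 40)) {
  stopifnot(length(reward_pellets) == 4, length(p_win) == 4,
            length(penalty_s) == 4,
            all(p_win >= 0 & p_win <= 1),
            all(penalty_s >= 0))
  tibble::tibble(
    option = paste0("P", 1:4),
    reward_pellets = as.integer(reward_pellets),
    p_win = p_win,
    penalty_s = penalty_s,
    p_penalty = 1 - p_win
  )
}

#' Expected pellets per trial under a schedule
#'
#' Long-run pellet yield per completed trial, `p_win * reward_pellets`.
#' Under the default schedule P2 yields 1.6 pellets/trial, making it the
#' best option even before accounting for the session time its short
#' penalties preserve.
#'
#' @param schedule A schedule tibble from [rgt_schedule()].
#' @return The schedule with an `expected_pellets` column appended.
#' @export
expected_pellets_per_trial <- function(schedule) {
  dplyr::mutate(schedule, expected_pellets = .data$p_win * .data$reward_pellets)
}

#' Session configuration
#'
#' Time parameters of one free-operant rGT session. Trials are initiated for
#' as long as the session clock has not expired; each trial consumes the
#' 5 s inter-trial interval plus either latencies (valid choice), the
#' time-out penalty (loss), a 5 s time-out (premature response during the
#' ITI), or the 10 s response window (omission).
#'
#' @param session_length_s Session duration in seconds (default 1800 = 30 min).
#' @param iti_s Inter-trial interval, seconds.
#' @param choice_latency_s,collect_latency_s Simulated latencies, seconds.
#' @param premature_prob,omission_prob Per-trial probability of a premature
#'   response / an omission. Default 0: model-facing simulations use valid
#'   choices only.
#' @param premature_timeout_s Time-out after a premature response, seconds.
#' @param omission_window_s Response window whose expiry logs an omission.
#' @param cue_variant Which outcomes are accompanied by the audiovisual cue:
#'   `"uncued"` (never), `"standard"` and `"reverse"` (wins only; they differ
#'   in how cue salience scales with reward size, metadata not modelled
#'   here), `"outcome"` (wins and losses), `"random50"` (any valid outcome
#'   with probability 0.5), `"loss"` (losses only).
#' @return A list of class `rgt_session_config`.
#' @export
session_config <- function(session_length_s = 1800, iti_s = 5,
                           choice_latency_s = 1, collect_latency_s = 1,
                           premature_prob = 0, omission_prob = 0,
                           premature_timeout_s = 5, omission_window_s = 10,
                           cue_variant = c("uncued", "standard", "reverse",
                                           "outcome", "random50", "loss")) {
  cue_variant <- match.arg(cue_variant)
  stopifnot(session_length_s > 0, iti_s >= 0, choice_latency_s >= 0,
            collect_latency_s >= 0,
            premature_prob >= 0, premature_prob <= 1,
            omission_prob >= 0, omission_prob <= 1,
            premature_timeout_s >= 0, omission_window_s >= 0)
  structure(
    list(session_length_s = session_length_s, iti_s = iti_s,
         choice_latency_s = choice_latency_s,
         collect_latency_s = collect_latency_s,
         premature_prob = premature_prob, omission_prob = omission_prob,
         premature_timeout_s = premature_timeout_s,
         omission_window_s = omission_window_s, cue_variant = cue_variant),
    class = "rgt_session_config")
}

#' Play a single rGT trial
#'
#' Resolves one valid choice against an option's reinforcement schedule:
#' a win with probability `p_win` delivering `reward_pellets`, otherwise a
#' loss imposing `penalty_s` seconds of time-out.
#'
#' @param schedule_row One row of a schedule tibble (the chosen option).
#' @return A list with `outcome` ("win"/"loss"), `pellets`, `penalty_s`.
#' @export
play_trial <- function(schedule_row) {
  if (runif(1) < schedule_row$p_win) {
    list(outcome = "win", pellets = schedule_row$reward_pellets, penalty_s = 0)
  } else {
    list(outcome = "loss", pellets = 0L, penalty_s = schedule_row$penalty_s)
  }
}

cue_rule <- function(cue_variant, outcome) {
  switch(cue_variant,
         uncued = FALSE,
         standard = outcome == "win",
         reverse = outcome == "win",
         outcome = outcome %in% c("win", "loss"),
         random50 = outcome %in% c("win", "loss") && runif(1) < 0.5,
         loss = outcome == "loss")
}

#' Run one simulated rGT session
#'
#' Drives a choice policy through the session engine: trials are initiated
#' while the session clock has not expired, and a trial that starts before
#' expiry is completed even if it finishes after (free-operant semantics).
#' Risky policies therefore complete fewer trials per session, because long
#' time-out penalties consume the clock.
#'
#' @param policy A function called as `policy(last_trial)` where
#'   `last_trial` is the previous trial's record as a one-row tibble (or
#'   `NULL` on the first trial); it must return the chosen option
#'   `"P1"`..`"P4"`. Stateful learning policies (see [rl_policy()]) keep
#'   their latent values in a closure.
#' @param schedule A schedule tibble from [rgt_schedule()].
#' @param config An [session_config()] object.
#' @param subject_id,session Identifiers stamped into the log.
#' @param task_variant Label stamped into the log (defaults to the cue
#'   variant).
#' @return A tibble of trial records with columns `subject_id`,
#'   `task_variant`, `session`, `trial_index`, `choice`, `outcome`,
#'   `pellets`, `penalty_s`, `cue_played`, `premature`, `omission`,
#'   `latency_choice_s`, `latency_collect_s`, `clock_s`.
#' @export
run_session <- function(policy, schedule = rgt_schedule(),
                        config = session_config(), subject_id = "s1",
                        session = 1L, task_variant = config$cue_variant) {
  if (!is.function(policy)) stop("`policy` must be a function", call. = FALSE)
  if (config$session_length_s <= 0) stop("session length must be positive", call. = FALSE)
  clock <- 0
  rows <- list()
  i <- 0L
  last <- NULL
  while (clock < config$session_length_s) {
    i <- i + 1L
    u <- runif(1)
    if (u < config$premature_prob) {
      dt <- config$iti_s + config$premature_timeout_s
      rows[[i]] <- list(trial_index = i, choice = NA_character_,
                        outcome = "premature", pellets = 0L, penalty_s = 0,
                        cue_played = FALSE,
                        latency_choice_s = NA_real_, latency_collect_s = NA_real_,
                        clock_s = clock)
    } else if (u < config$premature_prob + config$omission_prob) {
      dt <- config$iti_s + config$omission_window_s
      rows[[i]] <- list(trial_index = i, choice = NA_character_,
                        outcome = "omission", pellets = 0L, penalty_s = 0,
                        cue_played = FALSE,
                        latency_choice_s = NA_real_, latency_collect_s = NA_real_,
                        clock_s = clock)
    } else {
      choice <- policy(last)
      k <- match(choice, schedule$option)
      if (is.na(k)) stop("policy returned unknown option: ", choice, call. = FALSE)
      res <- play_trial(schedule[k, ])
      cue <- cue_rule(config$cue_variant, res$outcome)
      dt <- config$iti_s + config$choice_latency_s +
        if (res$outcome == "win") config$collect_latency_s else res$penalty_s
      rows[[i]] <- list(trial_index = i, choice = choice, outcome = res$outcome,
                        pellets = as.integer(res$pellets),
                        penalty_s = res$penalty_s, cue_played = cue,
                        latency_choice_s = config$choice_latency_s,
                        latency_collect_s =
                          if (res$outcome == "win") config$collect_latency_s else NA_real_,
                        clock_s = clock)
    }
    clock <- clock + dt
    last <- rows[[i]]
  }
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out,
                subject_id = subject_id,
                task_variant = task_variant,
                session = as.integer(session),
                premature = as.integer(.data$outcome == "premature"),
                omission = as.integer(.data$outcome == "omission"),
                .before = 1) |>
    dplyr::relocate("subject_id", "task_variant", "session", "trial_index",
                    "choice", "outcome", "pellets", "penalty_s", "cue_played",
                    "premature", "omission")
}
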