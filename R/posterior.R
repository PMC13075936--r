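#' Highest-density interval
#'
#' The narrowest interval containing `prob` of the sample mass, found by
#' the sorted-window algorithm: all windows of `ceiling(prob * n)`
#' consecutive order statistics are scanned and the shortest returned.
#' For unimodal posteriors every point inside has higher density than any
#' point outside.
#'
#' @param samples Numeric vector (>= 10 values for a meaningful interval).
#' @param prob Mass to cover, default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @export
hdi <- function(samples, prob = 0.95) {
  samples <- samples[is.finite(samples)]
  if (!length(samples)) stop("empty sample", call. = FALSE)
  stopifnot(prob > 0, prob <= 1)
  x <- sort(samples)
  n <- length(x)
  k <- min(n, max(1L, ceiling(prob * n)))
  if (k == n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(k):n] - x[seq_len(n - k + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k - 1])
}

#' Credible contrast between two groups' posterior parameter estimates
#'
#' Difference of the group-level posterior draws (a - b) on the natural
#' scale; the difference is called credible when the 95% HDI excludes zero.
#' Draw counts are matched by resampling the larger set when unequal.
#'
#' @param fit_a,fit_b `rgt_hierfit` objects for the two groups (same model).
#' @param parameter Parameter name present in both fits.
#' @param prob HDI mass, default 0.95.
#' @return One-row tibble: `parameter`, `mean_diff`, `hdi_low`, `hdi_high`,
#'   `credible`.
#' @export
group_contrast <- function(fit_a, fit_b, parameter, prob = 0.95) {
  da <- group_level_draws(fit_a, parameter)
  db <- group_level_draws(fit_b, parameter)
  n <- min(length(da), length(db))
  if (length(da) > n) da <- da[seq_len(n)]
  if (length(db) > n) db <- db[seq_len(n)]
  d <- da - db
  h <- hdi(d, prob)
  tibble::tibble(parameter = parameter, mean_diff = mean(d),
                 hdi_low = h[["lower"]], hdi_high = h[["upper"]],
                 credible = h[["lower"]] > 0 || h[["upper"]] < 0)
}

#' Contrast every shared parameter between two group fits
#'
#' @inheritParams group_contrast
#' @return Tibble with one row per parameter.
#' @export
group_contrast_table <- function(fit_a, fit_b, prob = 0.95) {
  purrr::map(fit_a$param_names, function(p) group_contrast(fit_a, fit_b, p, prob)) |>
    dplyr::bind_rows()
}

#' Posterior-predictive forward simulation of a cohort
#'
#' Simulates each subject's long-run behavior from its fitted point
#' estimates (posterior means by default): the standard probe is 40
#' sessions, after which the decision score of the final five sessions
#' summarises where learning settles. Per-subject seeds fan out from the
#' master seed.
#'
#' @param subject_params Tibble with `subject_id`, `model` and parameter
#'   columns ([subject_estimates()] output, or a synthetic truth table).
#' @param n_sessions Number of simulated sessions (default 40).
#' @param trials_per_session Trials per simulated session.
#' @param outcome_mode `"sampled"` or `"expected"` (see [simulate_agent()]).
#' @param seed Master seed.
#' @param schedule Schedule tibble.
#' @return Tibble of simulated trials for all subjects, including the
#'   per-trial choice-probability columns `p_P1..p_P4`.
#' @export
forward_simulate_cohort <- function(subject_params, n_sessions = 40,
                                    trials_per_session = 120,
                                    outcome_mode = c("sampled", "expected"),
                                    seed = 1, schedule = rgt_schedule()) {
  outcome_mode <- match.arg(outcome_mode)
  if (!nrow(subject_params)) stop("no subjects to simulate", call. = FALSE)
  purrr::map(seq_len(nrow(subject_params)), function(i) {
    row <- subject_params[i, ]
    set.seed((seed + i) %% .Machine$integer.max)
    sim <- simulate_agent(params_from_row(row), schedule, n_sessions,
                          trials_per_session, trials_mode = "fixed_n",
                          outcome_mode = outcome_mode)
    dplyr::mutate(sim$trials, subject_id = row$subject_id, .before = 1)
  }) |> dplyr::bind_rows()
}

#' Decision score of simulated sessions
#'
#' Scores each simulated subject over a late-session window (default
#' sessions 36-40). In `"probability"` mode the percent choice entering
#' the score is the mean of the per-trial softmax probabilities over the
#' window (variance-reduced); in `"realized"` mode it is computed from the
#' sampled choices, as for real data.
#'
#' @param sim Output of [forward_simulate_cohort()].
#' @param session_window Length-2 inclusive session range.
#' @param mode `"probability"` or `"realized"`.
#' @return Tibble: `subject_id`, `decision_score`.
#' @export
simulated_decision_scores <- function(sim, session_window = c(36, 40),
                                      mode = c("probability", "realized")) {
  mode <- match.arg(mode)
  w <- sim |> dplyr::filter(.data$session >= session_window[1],
                            .data$session <= session_window[2])
  if (!nrow(w)) stop("session window not covered by the simulation", call. = FALSE)
  if (mode == "probability") {
    w |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(paste0("p_P", 1:4)), mean),
                       .groups = "drop") |>
      dplyr::mutate(decision_score =
                      100 * (.data$p_P1 + .data$p_P2 - .data$p_P3 - .data$p_P4)) |>
      dplyr::select("subject_id", "decision_score")
  } else {
    w |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(decision_score = decision_score(
        choice_percentages_vec(.data$choice)), .groups = "drop")
  }
}

#' Regress a subject-level parameter estimate on final decision score
#'
#' Ordinary least squares of score on parameter with the slope's F-test
#' (`F = t^2` on 1 and n-2 degrees of freedom) — the per-parameter probe of
#' whether early-learning model parameters predict where risk preference
#' ends up.
#'
#' @param estimates Per-subject parameter values (predictor).
#' @param scores Per-subject final decision scores (response), same order.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `f_stat`,
#'   `df1`, `df2`, `p_value`, `n`.
#' @export
regress_param_vs_score <- function(estimates, scores) {
  stopifnot(length(estimates) == length(scores))
  if (length(estimates) < 3) stop("regression needs n >= 3", call. = FALSE)
  if (var(estimates) == 0) stop("zero variance in predictor", call. = FALSE)
  fit <- lm(scores ~ estimates)
  s <- summary(fit)
  f <- s$fstatistic
  tibble::tibble(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = s$r.squared,
                 f_stat = unname(f[1]), df1 = unname(f[2]), df2 = unname(f[3]),
                 p_value = unname(pf(f[1], f[2], f[3], lower.tail = FALSE)),
                 n = length(scores))
}
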