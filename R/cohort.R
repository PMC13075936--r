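#' Group-level hyperparameters for a synthetic cohort
#'
#' Describes one group of subjects for the synthetic-data generator:
#' per-parameter group mean and SD on the unconstrained scale (the same
#' scale the hierarchical model samples on), mirroring the partial-pooling
#' structure the inference assumes. Defaults are order-of-magnitude choices
#' for a task-naive rat cohort: mean inverse temperature around 2, reward
#' learning rate around 0.10, punishment learning rate around 0.15, cost
#' scaling around 0.1 pellets/s, unit-scale power curvature near 0.8, and
#' no offset. Individual values can be overridden through `mu`/`sd`.
#'
#' @param model Model name from [rl_models()].
#' @param n_subjects Number of subjects in the group (>= 2).
#' @param task_variant Group label stamped into generated logs.
#' @param mu,sd Named numeric vectors overriding the default unconstrained
#'   group means / SDs for any subset of the model's parameters. Remember
#'   the constraint transforms: learning-rate means live on the probit
#'   scale (`qnorm(eta)`), `beta`/`m`/`r`/`mRew` means on the log scale,
#'   `b` on the natural scale.
#' @return A list of class `rgt_hypers`.
#' @examples
#' cohort_hypers("nonlinear", 12, mu = c(eta_minus = qnorm(0.45)))
#' @export
cohort_hypers <- function(model, n_subjects, task_variant = "uncued",
                          mu = NULL, sd = NULL) {
  need <- model_param_names(model)
  mu0 <- c(beta = log(2), eta_plus = qnorm(0.10), eta_minus = qnorm(0.15),
           m = log(0.1), b = 8, r = log(0.65), mRew = 0)[need]
  sd0 <- c(beta = 0.3, eta_plus = 0.3, eta_minus = 0.3,
           m = 0.3, b = 3, r = 0.15, mRew = 0.2)[need]
  if (!is.null(mu)) {
    bad <- setdiff(names(mu), need)
    if (length(bad)) stop("unknown parameter(s) in mu: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    mu0[names(mu)] <- mu
  }
  if (!is.null(sd)) {
    bad <- setdiff(names(sd), need)
    if (length(bad)) stop("unknown parameter(s) in sd: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    sd0[names(sd)] <- sd
  }
  if (any(sd0 <= 0)) stop("group SDs must be positive", call. = FALSE)
  if (n_subjects < 2) stop("a group needs at least 2 subjects", call. = FALSE)
  structure(list(model = model, n_subjects = as.integer(n_subjects),
                 task_variant = task_variant, mu = mu0, sd = sd0),
            class = "rgt_hypers")
}

#' Draw subject-level parameters from group hyperparameters
#'
#' Subjects are sampled on the unconstrained scale,
#' `x_sp = mu_p + sd_p * z_sp` with standard-normal `z`, then mapped
#' through the same constraint transforms the inference uses (probit for
#' learning rates, exp for `beta`/`m`/`r`/`mRew`, identity for `b`). With
#' `sd -> 0` every subject collapses onto the transformed group means.
#'
#' @param hypers An [cohort_hypers()] object.
#' @param seed Integer seed (optional; the caller may manage the RNG).
#' @return A tibble: `subject_id`, `task_variant`, `model`, one column per
#'   parameter on the natural scale.
#' @export
sample_cohort_params <- function(hypers, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  need <- names(hypers$mu)
  z <- matrix(rnorm(hypers$n_subjects * length(need)),
              nrow = hypers$n_subjects,
              dimnames = list(NULL, need))
  un <- sweep(sweep(z, 2, hypers$sd, `*`), 2, hypers$mu, `+`)
  nat <- t(apply(un, 1, constrain_params, names = need))
  tibble::tibble(
    subject_id = sprintf("%s_%02d", hypers$task_variant, seq_len(hypers$n_subjects)),
    task_variant = hypers$task_variant,
    model = hypers$model
  ) |> dplyr::bind_cols(tibble::as_tibble(nat))
}

params_from_row <- function(row) {
  need <- model_param_names(row$model)
  do.call(rl_params, c(list(model = row$model), as.list(row[need])))
}

#' Generate trial logs for a cohort of RL agents
#'
#' Each subject plays the rGT with its own parameters: Q starts at zero and
#' carries across that subject's sessions. In `time_budget` mode (the
#' default, matching the 30-minute session) trial counts emerge from the
#' session clock, so risk-prone agents complete fewer trials; `fixed_n`
#' mode gives every session exactly `trials_per_session` trials and is much
#' faster. One master seed fans out per subject (`seed + subject index`) so
#' subject streams are independent and reproducible.
#'
#' @param params_tbl Subject parameter tibble from [sample_cohort_params()].
#' @param n_sessions Sessions per subject.
#' @param config Session configuration (`time_budget` mode).
#' @param seed Master integer seed.
#' @param trials_mode `"time_budget"` or `"fixed_n"`.
#' @param trials_per_session Trials per session in `fixed_n` mode.
#' @param schedule Schedule tibble.
#' @return A list of class `rgt_cohort`: `trials` (canonical trial-log
#'   tibble), `truth` (the parameter tibble), `seed`.
#' @export
generate_cohort_logs <- function(params_tbl, n_sessions = 5,
                                 config = session_config(), seed = 1,
                                 trials_mode = c("time_budget", "fixed_n"),
                                 trials_per_session = 120,
                                 schedule = rgt_schedule()) {
  trials_mode <- match.arg(trials_mode)
  stopifnot(n_sessions >= 1)
  logs <- purrr::map(seq_len(nrow(params_tbl)), function(i) {
    row <- params_tbl[i, ]
    set.seed((seed + i) %% .Machine$integer.max)
    pars <- params_from_row(row)
    if (trials_mode == "time_budget") {
      pol <- rl_policy(pars, schedule)
      purrr::map(seq_len(n_sessions), function(s) {
        run_session(pol, schedule, config, subject_id = row$subject_id,
                    session = s, task_variant = row$task_variant)
      }) |> dplyr::bind_rows()
    } else {
      sim <- simulate_agent(pars, schedule, n_sessions, trials_per_session,
                            trials_mode = "fixed_n")
      sim$trials |>
        dplyr::transmute(subject_id = row$subject_id,
                         task_variant = row$task_variant,
                         session = .data$session,
                         trial_index = .data$trial_index,
                         choice = .data$choice, outcome = .data$outcome,
                         pellets = as.integer(.data$pellets),
                         penalty_s = .data$penalty_s,
                         cue_played = FALSE, premature = 0L, omission = 0L,
                         latency_choice_s = NA_real_,
                         latency_collect_s = NA_real_)
    }
  })
  structure(list(trials = dplyr::bind_rows(logs), truth = params_tbl,
                 seed = seed), class = "rgt_cohort")
}

#' Two-group recovery cohort
#'
#' Convenience wrapper for the package's standard synthetic experiment: two
#' groups identical in every hyperparameter except the punishment learning
#' rate (`eta_minus` group means 0.15 vs 0.45 by default), the parameter
#' whose group differences the models are asked to detect and whose rank
#' order should mirror the groups' decision scores.
#'
#' @param n_subjects Subjects per group.
#' @param eta_minus Length-2 vector of group-level punishment learning
#'   rates (natural scale).
#' @param model Generating model.
#' @param n_sessions Sessions per subject.
#' @param seed Master seed.
#' @param ... Passed to [generate_cohort_logs()].
#' @return A list with elements `low` and `high`, each an `rgt_cohort`.
#' @export
two_group_cohort <- function(n_subjects = 12, eta_minus = c(0.15, 0.45),
                             model = "nonlinear", n_sessions = 5, seed = 1,
                             ...) {
  stopifnot(length(eta_minus) == 2)
  groups <- purrr::map2(eta_minus, c("low_em", "high_em"), function(em, lab) {
    hy <- cohort_hypers(model, n_subjects, task_variant = lab,
                        mu = c(eta_minus = qnorm(em)))
    pars <- sample_cohort_params(hy, seed = seed + 1000L * match(lab, c("low_em", "high_em")))
    generate_cohort_logs(pars, n_sessions = n_sessions,
                         seed = seed + 17L * match(lab, c("low_em", "high_em")),
                         ...)
  })
  names(groups) <- c("low", "high")
  groups
}
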