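#' The Q-learning model family
#'
#' Five models of trial-by-trial learning on the rGT. All share latent
#' Q-values per option (pellet-equivalent units, initialised at zero and
#' carried across sessions), softmax choice with inverse temperature `beta`,
#' and a delta-rule win update with learning rate `eta_plus` toward the
#' pellets earned. They differ in the target of the loss update with
#' learning rate `eta_minus`, i.e. in how a time-out penalty of `T` seconds
#' is converted into a pellet-equivalent cost:
#'
#' * `basic`: target 0 — penalty duration plays no explicit role.
#' * `scaled`: target `-m*T` — cost linear in duration (`m` pellets/s).
#' * `scaled_offset`: target `b - m*T` — linear with a global offset.
#' * `nonlinear`: target `b - T^r` — power-law curvature plus offset.
#' * `reward_scaled`: loss as `scaled`; win target `mRew * R` adds a linear
#'   reward-size scaling, a control for the extra flexibility the loss
#'   transforms enjoy.
#'
#' @return A tibble with `model`, `n_params`, and a list-column `params`
#'   naming each model's free parameters in canonical order.
#' @export
rl_models <- function() {
  tibble::tibble(
    model = c("basic", "scaled", "scaled_offset", "nonlinear", "reward_scaled"),
    n_params = c(3L, 4L, 5L, 5L, 5L),
    params = list(
      c("beta", "eta_plus", "eta_minus"),
      c("beta", "eta_plus", "eta_minus", "m"),
      c("beta", "eta_plus", "eta_minus", "m", "b"),
      c("beta", "eta_plus", "eta_minus", "b", "r"),
      c("beta", "eta_plus", "eta_minus", "m", "mRew")
    )
  )
}

model_id_int <- function(model) {
  i <- match(model, rl_models()$model)
  if (is.na(i)) stop("unknown model: ", model, call. = FALSE)
  i - 1L
}

model_param_names <- function(model) {
  rl_models()$params[[match(model, rl_models()$model)]]
}

# constraint transform code per parameter: exp for positive parameters,
# probit for learning rates, identity for the offset
param_trans_code <- function(names) {
  unname(vapply(names, function(p) {
    switch(p, beta = 0L, m = 0L, r = 0L, mRew = 0L,
           eta_plus = 1L, eta_minus = 1L, b = 2L)
  }, integer(1)))
}

constrain_params <- function(x, names) {
  code <- param_trans_code(names)
  out <- numeric(length(x))
  out[code == 0L] <- exp(x[code == 0L])
  out[code == 1L] <- pnorm(x[code == 1L])
  out[code == 2L] <- x[code == 2L]
  setNames(out, names)
}

#' Construct one subject's model parameters
#'
#' @param model One of `rl_models()$model`.
#' @param beta Inverse temperature, > 0.
#' @param eta_plus,eta_minus Reward / punishment learning rates in \[0, 1\].
#' @param m Pellets-per-second cost scaling, > 0 (scaled, scaled_offset,
#'   reward_scaled).
#' @param b Pellet-equivalent offset, real (scaled_offset, nonlinear).
#' @param r Power exponent, > 0 (nonlinear).
#' @param mRew Reward-size scaling, > 0 (reward_scaled).
#' @return A named list of class `rl_params` holding exactly the model's
#'   active parameters.
#' @examples
#' rl_params("nonlinear", beta = 2, eta_plus = 0.1, eta_minus = 0.3, b = 2, r = 0.8)
#' @export
rl_params <- function(model, beta, eta_plus, eta_minus,
                      m = NULL, b = NULL, r = NULL, mRew = NULL) {
  need <- model_param_names(model)
  supplied <- list(beta = beta, eta_plus = eta_plus, eta_minus = eta_minus,
                   m = m, b = b, r = r, mRew = mRew)
  vals <- supplied[need]
  missing <- need[vapply(vals, is.null, logical(1))]
  if (length(missing))
    stop("model '", model, "' requires parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(supplied)[!vapply(supplied, is.null, logical(1))], need)
  if (length(extra))
    stop("model '", model, "' does not use parameter(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  stopifnot(beta >= 0, eta_plus >= 0, eta_plus <= 1,
            eta_minus >= 0, eta_minus <= 1)
  structure(c(list(model = model), vals), class = "rl_params")
}

param_vector <- function(params) {
  unlist(params[model_param_names(params$model)])
}

#' Softmax choice probabilities
#'
#' `p_x = exp(beta * Q_x) / sum_y exp(beta * Q_y)`, computed with
#' max-subtraction so large `beta * Q` cannot overflow. At `beta = 0` (or
#' all-equal Q) choice is uniform over the four options.
#'
#' @param q Numeric 4-vector of latent values.
#' @param beta Inverse temperature, >= 0.
#' @return Probability 4-vector summing to 1.
#' @export
softmax_probs <- function(q, beta) {
  if (any(!is.finite(q))) stop("q must be finite", call. = FALSE)
  stopifnot(length(q) == 4, beta >= 0)
  z <- pmin(pmax(beta * q, -700), 700)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Delta-rule update after a win
#'
#' The chosen option's Q moves toward the pellets earned:
#' `Q <- Q + eta_plus * (target - Q)` with target `R` (or `mRew * R` for the
#' reward-scaled model). Unchosen options are untouched.
#'
#' @param q Q 4-vector.
#' @param choice Option index 1..4 (or "P1".."P4").
#' @param r_tr Pellets earned, > 0.
#' @param params An [rl_params()] object.
#' @return Updated Q 4-vector.
#' @export
update_win <- function(q, choice, r_tr, params) {
  if (r_tr <= 0) stop("a win must deliver pellets", call. = FALSE)
  k <- choice_index(choice)
  target <- if (params$model == "reward_scaled") params$mRew * r_tr else r_tr
  q[k] <- q[k] + params$eta_plus * (target - q[k])
  q
}

#' Delta-rule update after a loss
#'
#' The chosen option's Q moves toward the model's pellet-equivalent cost of
#' a `t_tr`-second time-out: 0 (basic), `-m*t` (scaled, reward_scaled),
#' `b - m*t` (scaled_offset), or `b - t^r` (nonlinear).
#'
#' @param q Q 4-vector.
#' @param choice Option index 1..4 (or "P1".."P4").
#' @param t_tr Penalty duration in seconds, >= 0.
#' @param params An [rl_params()] object.
#' @return Updated Q 4-vector.
#' @export
update_loss <- function(q, choice, t_tr, params) {
  if (t_tr < 0) stop("penalty duration cannot be negative", call. = FALSE)
  k <- choice_index(choice)
  target <- switch(params$model,
                   basic = 0,
                   scaled = -params$m * t_tr,
                   scaled_offset = params$b - params$m * t_tr,
                   nonlinear = params$b - t_tr^params$r,
                   reward_scaled = -params$m * t_tr)
  q[k] <- q[k] + params$eta_minus * (target - q[k])
  q
}

choice_index <- function(choice) {
  k <- if (is.character(choice)) match(choice, paste0("P", 1:4)) else as.integer(choice)
  if (is.na(k) || k < 1 || k > 4) stop("invalid choice: ", choice, call. = FALSE)
  k
}

#' Sequential log-likelihood of one subject's choices
#'
#' Replays the subject's valid trials in order (sorted by session then trial
#' index): at each trial the softmax probability of the observed choice is
#' scored, then the chosen Q is updated by the observed outcome. Q starts at
#' zero and persists across session boundaries, so the trials behave as one
#' concatenated session.
#'
#' @param params An [rl_params()] object.
#' @param trials A trial-log tibble (only `outcome %in% c("win", "loss")`
#'   rows are permitted; filter with [valid_choices()]).
#' @return A list with `total` (sum) and `pointwise` (per-trial vector).
#' @export
subject_loglik <- function(params, trials) {
  trials <- check_modeling_trials(trials)
  pw <- cpp_pointwise_loglik(choice_index_vec(trials$choice),
                             as.integer(trials$outcome == "win"),
                             as.numeric(trials$pellets),
                             as.numeric(trials$penalty_s),
                             model_id_int(params$model),
                             param_vector(params))
  list(total = sum(pw), pointwise = as.numeric(pw))
}

choice_index_vec <- function(choice) {
  if (is.character(choice)) match(choice, paste0("P", 1:4)) else as.integer(choice)
}

check_modeling_trials <- function(trials) {
  if (!all(trials$outcome %in% c("win", "loss")))
    stop("modeling trials must contain valid choices only (win/loss); ",
         "filter premature/omission rows first", call. = FALSE)
  if (!is.null(trials$session)) {
    ord <- order(trials$session, trials$trial_index)
    if (!identical(ord, seq_along(ord)))
      stop("trials must be sorted by (session, trial_index)", call. = FALSE)
  }
  trials
}

#' Keep only the trials the models are fit to
#'
#' Valid choices (win or loss outcomes) from sessions inside `sessions`;
#' premature responses and omissions are dropped.
#'
#' @param trials Trial-log tibble.
#' @param sessions Session window, default the first five sessions.
#' @return Filtered tibble sorted by subject, session, trial.
#' @export
valid_choices <- function(trials, sessions = 1:5) {
  trials |>
    dplyr::filter(.data$outcome %in% c("win", "loss"),
                  .data$session %in% sessions) |>
    dplyr::arrange(.data$subject_id, .data$session, .data$trial_index)
}

#' Simulate an RL agent on the rGT
#'
#' Forward-simulates choices from a parameterised model. In `fixed_n` mode
#' every session holds `trials_per_session` trials; in `time_budget` mode
#' the session engine of [run_session()] decides trial counts from the
#' session clock. Outcomes are sampled from the schedule by default;
#' `outcome_mode = "expected"` propagates the probability-weighted update
#' instead (choices are still sampled), a variance-reduced variant.
#'
#' @param params An [rl_params()] object.
#' @param schedule Schedule tibble.
#' @param n_sessions Number of sessions.
#' @param trials_per_session Trials per session (`fixed_n` mode).
#' @param trials_mode `"fixed_n"` or `"time_budget"`.
#' @param outcome_mode `"sampled"` or `"expected"` (`fixed_n` only).
#' @param config Session configuration (`time_budget` mode).
#' @param q0 Initial Q 4-vector (zeros: a task-naive subject).
#' @return A list with `trials` (tibble incl. per-trial softmax
#'   probabilities `p_P1..p_P4` evaluated before each choice) and `q_final`.
#' @export
simulate_agent <- function(params, schedule = rgt_schedule(), n_sessions = 1,
                           trials_per_session = 120,
                           trials_mode = c("fixed_n", "time_budget"),
                           outcome_mode = c("sampled", "expected"),
                           config = session_config(), q0 = rep(0, 4)) {
  trials_mode <- match.arg(trials_mode)
  outcome_mode <- match.arg(outcome_mode)
  stopifnot(n_sessions >= 1)
  if (trials_mode == "fixed_n") {
    sched <- as.matrix(schedule[, c("reward_pellets", "p_win", "penalty_s",
                                    "p_penalty")])
    res <- cpp_simulate_agent(model_id_int(params$model), param_vector(params),
                              sched, as.integer(n_sessions),
                              as.integer(trials_per_session),
                              as.integer(outcome_mode == "expected"), q0)
    probs <- res$probs
    colnames(probs) <- paste0("p_", schedule$option)
    trials <- tibble::tibble(
      session = res$session, trial_index = res$trial,
      choice = paste0("P", res$choice),
      outcome = ifelse(is.na(res$win), "expected",
                       ifelse(res$win == 1, "win", "loss")),
      pellets = res$pellets, penalty_s = res$penalty_s
    ) |> dplyr::bind_cols(tibble::as_tibble(probs))
    # final Q by replay (cheap relative to simulation)
    q <- q0
    if (outcome_mode == "sampled") {
      for (t in seq_len(nrow(trials))) {
        if (trials$outcome[t] == "win")
          q <- update_win(q, trials$choice[t], trials$pellets[t], params)
        else q <- update_loss(q, trials$choice[t], trials$penalty_s[t], params)
      }
    } else q <- rep(NA_real_, 4)
    list(trials = trials, q_final = q)
  } else {
    pol <- rl_policy(params, schedule, q0 = q0)
    logs <- purrr::map(seq_len(n_sessions), function(s) {
      run_session(pol, schedule, config, subject_id = "agent", session = s)
    })
    list(trials = dplyr::bind_rows(logs), q_final = environment(pol)$q)
  }
}

#' Stateful RL choice policy for the session engine
#'
#' Returns a closure usable as the `policy` argument of [run_session()]: it
#' keeps the agent's Q-values in its environment, updates them from each
#' completed trial it is shown, and samples the next choice from the
#' softmax. Reusing one policy across successive [run_session()] calls
#' carries Q across sessions, as the models assume.
#'
#' @param params An [rl_params()] object.
#' @param schedule Schedule tibble (for option labels).
#' @param q0 Initial Q 4-vector.
#' @return A function `policy(last_trial) -> option label`.
#' @export
rl_policy <- function(params, schedule = rgt_schedule(), q0 = rep(0, 4)) {
  q <- q0
  opts <- schedule$option
  function(last_trial) {
    if (!is.null(last_trial) && last_trial$outcome %in% c("win", "loss")) {
      if (last_trial$outcome == "win")
        q <<- update_win(q, last_trial$choice, last_trial$pellets, params)
      else
        q <<- update_loss(q, last_trial$choice, last_trial$penalty_s, params)
    }
    p <- softmax_probs(q, params$beta)
    sample(opts, 1, prob = p)
  }
}
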