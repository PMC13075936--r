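# Independent oracles used across tests. These deliberately avoid the code
# paths they check: the likelihood oracle replays the whole history from
# Q = 0 for every trial instead of carrying state, and the WAIC oracle is a
# direct transcription of the defining formula.

# from-scratch replay likelihood: for trial t, re-apply updates 1..t-1
# starting at zero, then evaluate the softmax fresh (O(T^2), no state reuse)
oracle_pointwise_loglik <- function(params, trials) {
  n <- nrow(trials)
  out <- numeric(n)
  for (t in seq_len(n)) {
    q <- rep(0, 4)
    if (t > 1) {
      for (u in seq_len(t - 1)) {
        if (trials$outcome[u] == "win") {
          q <- update_win(q, trials$choice[u], trials$pellets[u], params)
        } else {
          q <- update_loss(q, trials$choice[u], trials$penalty_s[u], params)
        }
      }
    }
    p <- softmax_probs(q, params$beta)
    out[t] <- log(p[match(trials$choice[t], paste0("P", 1:4))])
  }
  out
}

oracle_waic <- function(ll) {
  n <- ncol(ll)
  elpd_i <- numeric(n); p_i <- numeric(n)
  for (i in seq_len(n)) {
    elpd_i[i] <- log(mean(exp(ll[, i]))) - var(ll[, i])
    p_i[i] <- var(ll[, i])
  }
  list(elpd = sum(elpd_i), p_waic = sum(p_i), waic = -2 * sum(elpd_i),
       se = sqrt(n * var(-2 * elpd_i)))
}

# random valid-trial log with choices/outcomes drawn uniformly at random
random_trials <- function(n, seed, schedule = rgt_schedule()) {
  set.seed(seed)
  k <- sample.int(4, n, replace = TRUE)
  win <- runif(n) < 0.5
  tibble::tibble(
    subject_id = "r1", session = 1L, trial_index = seq_len(n),
    choice = paste0("P", k),
    outcome = ifelse(win, "win", "loss"),
    pellets = ifelse(win, schedule$reward_pellets[k], 0L),
    penalty_s = ifelse(win, 0, schedule$penalty_s[k])
  )
}

random_params <- function(model, seed) {
  set.seed(seed)
  rl_params(model,
            beta = runif(1, 0.2, 5), eta_plus = runif(1, 0.02, 0.9),
            eta_minus = runif(1, 0.02, 0.9),
            m = if ("m" %in% model_names(model)) runif(1, 0.02, 0.5) else NULL,
            b = if ("b" %in% model_names(model)) runif(1, -5, 10) else NULL,
            r = if ("r" %in% model_names(model)) runif(1, 0.3, 1.2) else NULL,
            mRew = if ("mRew" %in% model_names(model)) runif(1, 0.5, 2) else NULL)
}

model_names <- function(model) {
  rl_models()$params[[match(model, rl_models()$model)]]
}

# small synthetic cohort in fast fixed-trial mode, for inference tests
small_cohort <- function(n_subjects = 6, n_sessions = 2, seed = 1,
                         model = "basic", trials_per_session = 80,
                         eta_minus = 0.2) {
  hy <- cohort_hypers(model, n_subjects, task_variant = "uncued",
                      mu = c(eta_minus = qnorm(eta_minus)))
  pars <- sample_cohort_params(hy, seed = seed)
  generate_cohort_logs(pars, n_sessions = n_sessions, seed = seed + 7,
                       trials_mode = "fixed_n",
                       trials_per_session = trials_per_session)
}
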