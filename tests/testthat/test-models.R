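test_that("softmax has the symmetric and greedy limits and is overflow-stable", {
  expect_equal(softmax_probs(c(0, 0, 0, 0), 3), rep(0.25, 4))
  expect_equal(softmax_probs(c(5, -2, 1, 0), 0), rep(0.25, 4))
  # direct evaluation of the formula
  p <- softmax_probs(c(2, 1, 0, 0), 1)
  ref <- exp(c(2, 1, 0, 0)) / sum(exp(c(2, 1, 0, 0)))
  expect_equal(p, ref, tolerance = 1e-12)
  expect_equal(round(p, 4), c(0.6103, 0.2245, 0.0826, 0.0826))
  # large beta*Q must not overflow and must still sum to one
  for (q in list(c(700, 0, -700, 1), c(1e4, 1e4, -1e4, 0))) {
    p <- softmax_probs(q, 1)
    expect_true(all(is.finite(p)))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  expect_error(softmax_probs(c(Inf, 0, 0, 0), 1), "finite")
})

test_that("win update follows the delta rule and its reward-scaled variant", {
  p <- rl_params("basic", beta = 1, eta_plus = 0.5, eta_minus = 0.3)
  expect_equal(update_win(rep(0, 4), "P2", 2, p), c(0, 1, 0, 0))
  p0 <- rl_params("basic", beta = 1, eta_plus = 0, eta_minus = 0.3)
  expect_equal(update_win(c(1, 2, 3, 4), "P3", 3, p0), c(1, 2, 3, 4))
  # mRew = 1 reduces exactly to the plain delta rule
  prs <- rl_params("reward_scaled", beta = 1, eta_plus = 0.37, eta_minus = 0.3,
                   m = 0.1, mRew = 1)
  pb <- rl_params("basic", beta = 1, eta_plus = 0.37, eta_minus = 0.3)
  q <- c(0.5, -1, 2, 0)
  for (k in 1:4) for (R in 1:4)
    expect_equal(update_win(q, k, R, prs), update_win(q, k, R, pb))
  expect_error(update_win(rep(0, 4), "P1", 0, p), "pellets")
})

test_that("loss updates implement each model's penalty transform", {
  pb <- rl_params("basic", beta = 1, eta_plus = 0.1, eta_minus = 0.5)
  expect_equal(update_loss(c(1, 1, 1, 1), "P1", 40, pb), c(0.5, 1, 1, 1))
  ps <- rl_params("scaled", beta = 1, eta_plus = 0.1, eta_minus = 0.5, m = 0.1)
  expect_equal(update_loss(rep(0, 4), "P4", 40, ps)[4], 0.5 * (-0.1 * 40))
  pso <- rl_params("scaled_offset", beta = 1, eta_plus = 0.1, eta_minus = 0.5,
                   m = 0.2, b = 3)
  expect_equal(update_loss(rep(0, 4), "P3", 30, pso)[3], 0.5 * (3 - 0.2 * 30))
  pn <- rl_params("nonlinear", beta = 1, eta_plus = 0.1, eta_minus = 0.5,
                  b = 2, r = 0.5)
  expect_equal(update_loss(rep(0, 4), "P3", 30, pn)[3], 0.5 * (2 - 30^0.5))
  expect_error(update_loss(rep(0, 4), "P1", -1, pb), "negative")
})

test_that("rl_params enforces each model's exact parameter set", {
  expect_error(rl_params("basic", beta = 1, eta_plus = 0.1, eta_minus = 0.1,
                         m = 0.1), "does not use")
  expect_error(rl_params("nonlinear", beta = 1, eta_plus = 0.1,
                         eta_minus = 0.1, b = 1), "requires")
  expect_equal(rl_models()$n_params, c(3L, 4L, 5L, 5L, 5L))
})

test_that("sequential log-likelihood equals the from-scratch replay oracle", {
  for (seed in 1:20) {
    model <- rl_models()$model[(seed %% 5) + 1]
    params <- random_params(model, seed + 100)
    trials <- random_trials(200, seed)
    got <- subject_loglik(params, trials)
    want <- oracle_pointwise_loglik(params, trials)
    expect_equal(got$pointwise, want, tolerance = 1e-10)
    expect_equal(got$total, sum(want), tolerance = 1e-10)
  }
})

test_that("log-likelihood has the uniform-choice limits", {
  trials <- random_trials(50, 1)
  p0 <- rl_params("basic", beta = 0, eta_plus = 0.3, eta_minus = 0.3)
  expect_equal(subject_loglik(p0, trials)$total, 50 * log(0.25), tolerance = 1e-12)
  one <- random_trials(1, 2)
  for (eta in c(0, 0.5, 1)) {
    p <- rl_params("basic", beta = 3, eta_plus = eta, eta_minus = eta)
    expect_equal(subject_loglik(p, one)$total, log(0.25), tolerance = 1e-12)
  }
})

test_that("Q persists across session boundaries (concatenated-session rule)", {
  params <- rl_params("basic", beta = 2, eta_plus = 0.4, eta_minus = 0.4)
  tr <- random_trials(60, 3)
  split <- dplyr::mutate(tr, session = rep(1:3, each = 20L),
                         trial_index = rep(1:20, 3))
  expect_equal(subject_loglik(params, split)$pointwise,
               subject_loglik(params, tr)$pointwise, tolerance = 1e-12)
})

test_that("model nesting identities hold pointwise on random trials", {
  trials <- random_trials(1000, 77)
  set.seed(42)
  for (i in 1:5) {
    beta <- runif(1, 0.2, 4); ep <- runif(1, 0.05, 0.8); em <- runif(1, 0.05, 0.8)
    m <- runif(1, 0.02, 0.5)
    scaled <- rl_params("scaled", beta = beta, eta_plus = ep, eta_minus = em, m = m)
    so0 <- rl_params("scaled_offset", beta = beta, eta_plus = ep, eta_minus = em,
                     m = m, b = 0)
    expect_equal(subject_loglik(so0, trials)$pointwise,
                 subject_loglik(scaled, trials)$pointwise, tolerance = 1e-10)
    nl0 <- rl_params("nonlinear", beta = beta, eta_plus = ep, eta_minus = em,
                     b = 0, r = 1)
    scaled1 <- rl_params("scaled", beta = beta, eta_plus = ep, eta_minus = em, m = 1)
    expect_equal(subject_loglik(nl0, trials)$pointwise,
                 subject_loglik(scaled1, trials)$pointwise, tolerance = 1e-10)
    rs1 <- rl_params("reward_scaled", beta = beta, eta_plus = ep, eta_minus = em,
                     m = m, mRew = 1)
    expect_equal(subject_loglik(rs1, trials)$pointwise,
                 subject_loglik(scaled, trials)$pointwise, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to consistent option relabeling", {
  params <- random_params("nonlinear", 5)
  trials <- random_trials(300, 6)
  perm <- c(3L, 1L, 4L, 2L)  # P1->P3, P2->P1, P3->P4, P4->P2
  sched <- rgt_schedule()
  k <- match(trials$choice, sched$option)
  relabeled <- dplyr::mutate(trials, choice = paste0("P", perm[k]))
  # under relabeled options the schedule is irrelevant to the likelihood:
  # pellets/penalties travel with the trials
  expect_equal(subject_loglik(params, relabeled)$pointwise,
               subject_loglik(params, trials)$pointwise, tolerance = 1e-12)
})

test_that("Q stays within the envelope of observed update targets", {
  for (seed in 1:5) {
    params <- random_params("scaled_offset", seed + 40)
    trials <- random_trials(400, seed + 50)
    q <- rep(0, 4)
    targets <- c(0)  # initialization
    for (t in seq_len(nrow(trials))) {
      if (trials$outcome[t] == "win") {
        targets <- c(targets, trials$pellets[t])
        q <- update_win(q, trials$choice[t], trials$pellets[t], params)
      } else {
        targets <- c(targets, params$b - params$m * trials$penalty_s[t])
        q <- update_loss(q, trials$choice[t], trials$penalty_s[t], params)
      }
      expect_true(all(q >= min(targets) - 1e-12 & q <= max(targets) + 1e-12))
    }
  }
})

test_that("agent simulation is deterministic under a seed and uniform without learning", {
  p <- rl_params("basic", beta = 4, eta_plus = 0, eta_minus = 0)
  set.seed(9)
  sim <- simulate_agent(p, n_sessions = 2, trials_per_session = 300)
  probs <- as.matrix(sim$trials[, paste0("p_P", 1:4)])
  expect_true(all(probs == 0.25))
  frac <- table(factor(sim$trials$choice, paste0("P", 1:4))) / 600
  expect_true(all(abs(frac - 0.25) < 3 * sqrt(0.25 * 0.75 / 600)))

  set.seed(123); a <- simulate_agent(random_params("scaled", 1), n_sessions = 3)
  set.seed(123); b <- simulate_agent(random_params("scaled", 1), n_sessions = 3)
  expect_identical(a, b)
})

test_that("greedy agents exploit a pre-seeded Q advantage", {
  p <- rl_params("basic", beta = 50, eta_plus = 0, eta_minus = 0)
  set.seed(4)
  sim <- simulate_agent(p, n_sessions = 1, trials_per_session = 100,
                        q0 = c(0, 5, 0, 0))
  expect_true(all(sim$trials$choice == "P2"))
})

test_that("weak-penalty agents (large offset) end up riskier than strong-penalty ones", {
  # the punishment-cost offset is the lever on long-run risk preference
  score_for <- function(b, seed) {
    p <- rl_params("nonlinear", beta = 2, eta_plus = 0.1, eta_minus = 0.3,
                   b = b, r = 0.65)
    set.seed(seed)
    sim <- simulate_agent(p, n_sessions = 10, trials_per_session = 100)
    pr <- dplyr::filter(sim$trials, session > 8)
    100 * (mean(pr$p_P1) + mean(pr$p_P2) - mean(pr$p_P3) - mean(pr$p_P4))
  }
  weak <- vapply(1:25, function(s) score_for(14, s), numeric(1))
  strong <- vapply(1:25, function(s) score_for(0, s), numeric(1))
  expect_lt(mean(weak), mean(strong))
})
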