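test_that("split R-hat separates converged from disjoint chains", {
  set.seed(1)
  same <- cbind(rnorm(4000), rnorm(4000))
  v <- rhat(same)
  expect_gte(v, 0.99)  # finite-sample split R-hat may dip just below 1
  expect_lte(v, 1.01)
  # hand-computed oracle on 8 fixed numbers: chains at 0 and 10
  ch <- cbind(c(-1, 1, -1, 1), c(9, 11, 9, 11))
  expect_gt(rhat(ch), 1.1)
  # split detection: a single trend inside each chain
  trend <- cbind(1:1000, 1:1000)
  expect_gt(rhat(trend), 1.1)
  expect_warning(v2 <- rhat(cbind(rep(3, 10), rep(3, 10))), "undefined")
  expect_true(is.na(v2))
  expect_error(rhat(matrix(1:3, ncol = 1)), "chains")
})

test_that("WAIC matches the pointwise formula oracle", {
  set.seed(8)
  for (i in 1:5) {
    ll <- matrix(rnorm(5 * 3, mean = -1), nrow = 5)
    got <- waic(ll)
    want <- oracle_waic(ll)
    expect_equal(got$waic, want$waic, tolerance = 1e-10)
    expect_equal(got$elpd, want$elpd, tolerance = 1e-10)
    expect_equal(got$p_waic, want$p_waic, tolerance = 1e-10)
    expect_equal(got$se, want$se, tolerance = 1e-10)
  }
})

test_that("WAIC penalty vanishes for a point posterior and doubles with the data", {
  ll <- matrix(rep(c(-1.2, -0.7, -2.1), each = 4), nrow = 4)
  got <- waic(ll)
  expect_equal(got$p_waic, 0)
  expect_equal(got$waic, -2 * sum(ll[1, ]))
  set.seed(2)
  ll2 <- matrix(rnorm(40, -1), nrow = 8)
  expect_equal(waic(cbind(ll2, ll2))$waic, 2 * waic(ll2)$waic, tolerance = 1e-10)
  expect_error(waic(matrix(c(1, NA), 2, 1)), "non-finite|draws")
})

test_that("paired WAIC differences are zero against self and need matched points", {
  set.seed(3)
  ll <- matrix(rnorm(60, -1), nrow = 6)
  w <- waic(ll)
  d <- waic_difference(w, w)
  expect_equal(d$delta_waic, 0)
  expect_equal(d$se, 0)
  expect_error(waic_difference(w, waic(ll[, 1:5])), "same data")
})

test_that("MLE recovers generating parameters at large n", {
  p_true <- rl_params("basic", beta = 2, eta_plus = 0.4, eta_minus = 0.2)
  set.seed(14)
  sim <- simulate_agent(p_true, n_sessions = 1, trials_per_session = 2000)
  tr <- dplyr::mutate(sim$trials, subject_id = "s1")
  fit <- fit_rgt_mle(tr, "basic", seed = 2, sessions = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta - 2), 0.5)
  expect_lt(abs(fit$eta_plus - 0.4), 0.1)
})

test_that("a single trial is flat in the learning rates and flagged low-information", {
  one <- random_trials(1, 4)
  fit <- fit_rgt_mle(one, "basic", seed = 1, sessions = 1)
  expect_equal(fit$loglik, log(0.25), tolerance = 1e-6)
  expect_true(fit$low_information)
})

test_that("nested models never fit worse than their special cases", {
  co <- small_cohort(n_subjects = 2, n_sessions = 2, seed = 9, model = "scaled")
  f_s <- fit_rgt_mle(co$trials, "scaled", n_starts = 25, seed = 3)
  f_so <- fit_rgt_mle(co$trials, "scaled_offset", n_starts = 25, seed = 3)
  expect_true(all(f_so$loglik >= f_s$loglik - 1e-3))
})

test_that("hierarchical fitting is deterministic under identical seeds", {
  co <- small_cohort(n_subjects = 4, n_sessions = 1, seed = 6,
                     trials_per_session = 60)
  cfg <- mcmc_config(n_chains = 2, n_warmup = 150, n_samples = 100, thin = 1,
                     warmup_cap = 150, seed = 42)
  f1 <- suppressWarnings(fit_rgt_hier(co$trials, "basic", cfg, sessions = 1))
  f2 <- suppressWarnings(fit_rgt_hier(co$trials, "basic", cfg, sessions = 1))
  expect_identical(f1$group_mu, f2$group_mu)
  expect_identical(f1$subject_draws, f2$subject_draws)
  expect_identical(f1$pointwise_loglik, f2$pointwise_loglik)
})

test_that("posterior structure carries the advertised shapes", {
  co <- small_cohort(n_subjects = 4, n_sessions = 1, seed = 16,
                     trials_per_session = 60)
  cfg <- mcmc_config(n_chains = 2, n_warmup = 200, n_samples = 120, thin = 1,
                     warmup_cap = 200, seed = 3)
  f <- suppressWarnings(fit_rgt_hier(co$trials, "scaled", cfg, sessions = 1))
  expect_equal(dim(f$group_mu), c(120, 2, 4))
  expect_equal(dim(f$subject_draws)[3], 4 * 4)
  expect_equal(ncol(f$pointwise_loglik), 4 * 60)
  expect_equal(nrow(f$pointwise_loglik), 240)
  expect_true(all(is.finite(f$pointwise_loglik)))
  g <- glance(f)
  expect_equal(g$n_points, 240)
  td <- tidy(f)
  expect_equal(td$parameter, c("beta", "eta_plus", "eta_minus", "m"))
  expect_true(all(td$hdi_low <= td$estimate & td$estimate <= td$hdi_high))
  expect_error(fit_rgt_hier(co$trials[co$trials$subject_id ==
                                        co$trials$subject_id[1], ],
                            "basic", cfg, sessions = 1), "2 subjects")
})

test_that("hierarchical and MLE subject estimates agree in rank order", {
  co <- small_cohort(n_subjects = 8, n_sessions = 2, seed = 19,
                     model = "basic", trials_per_session = 120)
  cfg <- mcmc_config(preset = "desk", seed = 7)
  f <- suppressWarnings(fit_rgt_hier(co$trials, "basic", cfg, sessions = 1:2))
  est <- subject_estimates(f)
  mle <- fit_rgt_mle(co$trials, "basic", seed = 5, sessions = 1:2)
  mle <- mle[match(est$subject_id, mle$subject_id), ]
  expect_gte(cor(est$eta_minus, mle$eta_minus, method = "spearman"), 0.5)
  expect_gte(cor(est$eta_plus, mle$eta_plus, method = "spearman"), 0.5)
})

test_that("prior-predictive cohorts span both risk statuses", {
  # weakly-informative hypers must not force one sign of decision score
  hy <- cohort_hypers("nonlinear", 24)
  co <- generate_cohort_logs(sample_cohort_params(hy, 77), n_sessions = 8,
                             seed = 78, trials_mode = "fixed_n",
                             trials_per_session = 80)
  sc <- behavior_summary(co$trials, sessions = 6:8)$decision_score
  expect_true(any(sc > 0) && any(sc < 0))
})
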