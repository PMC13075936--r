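fake_trials <- function(choices, outcomes = NULL, session = 1L) {
  n <- length(choices)
  if (is.null(outcomes)) outcomes <- rep("win", n)
  tibble::tibble(subject_id = "s", session = session, trial_index = seq_len(n),
                 choice = choices, outcome = outcomes,
                 pellets = ifelse(outcomes == "win", 1L, 0L),
                 penalty_s = ifelse(outcomes == "loss", 5, 0),
                 latency_choice_s = 1, latency_collect_s = 1)
}

test_that("choice percentages use valid choices only and sum to 100", {
  tr <- fake_trials(c(rep("P2", 8), rep("P1", 2)))
  expect_equal(unname(choice_percentages(tr)), c(20, 80, 0, 0))
  one <- fake_trials("P4")
  expect_equal(unname(choice_percentages(one)), c(0, 0, 0, 100))
  mixed <- fake_trials(c("P1", NA, "P2"), c("win", "premature", "loss"))
  expect_equal(sum(choice_percentages(mixed)), 100)
  expect_equal(unname(choice_percentages(mixed)), c(50, 50, 0, 0))
  expect_error(choice_percentages(fake_trials(NA_character_, "omission")),
               "no valid choices")
  set.seed(21)
  unif <- fake_trials(sample(paste0("P", 1:4), 1000, replace = TRUE))
  expect_true(all(abs(choice_percentages(unif) - 25) <
                    300 * sqrt(0.25 * 0.75 / 1000)))
})

test_that("decision score is the optimal-minus-risky percent difference", {
  expect_equal(decision_score(c(30, 40, 20, 10)), 40)
  expect_equal(decision_score(c(25, 25, 25, 25)), 0)
  expect_equal(decision_score(c(0, 0, 0, 100)), -100)
  expect_error(decision_score(c(50, 50, 50, 50)), "summing to 100")
  # invariance to trial order
  tr <- fake_trials(c(rep("P1", 3), rep("P4", 7)))
  shuffled <- tr[sample(nrow(tr)), ]
  expect_equal(decision_score(choice_percentages(tr)),
               decision_score(choice_percentages(shuffled)))
})

test_that("risk status splits on the sign of the score with zero -> optimal", {
  expect_equal(classify_risk_status(40), "optimal")
  expect_equal(classify_risk_status(-10), "risk_preferring")
  expect_equal(classify_risk_status(0), "optimal")
  expect_equal(classify_risk_status(c(5, -5)), c("optimal", "risk_preferring"))
})

test_that("premature rate uses initiated trials as the denominator", {
  tr <- fake_trials(c(rep("P1", 95), rep(NA_character_, 5)),
                    c(rep("win", 95), rep("premature", 5)))
  expect_equal(premature_rate(tr), 5)
  expect_equal(premature_rate(fake_trials("P1")), 0)
  all_pre <- fake_trials(rep(NA_character_, 4), rep("premature", 4))
  expect_equal(premature_rate(all_pre), 100)
})

test_that("arcsine transform hits its closed-form values and is increasing", {
  expect_equal(arcsine_transform(100), pi / 2)
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(25), pi / 6)
  expect_equal(arcsine_transform(50), asin(sqrt(0.5)))
  x <- seq(0.5, 99.5, by = 0.5)
  expect_true(all(diff(arcsine_transform(x)) > 0))
  expect_error(arcsine_transform(101), "0, 100")
})

test_that("stable window returns the latest stable k sessions", {
  flat <- tidyr::expand_grid(subject_id = paste0("s", 1:6), session = 1:10) |>
    dplyr::mutate(score = 10)
  expect_equal(stable_window(flat), 7:10)
  # monotone rise then plateau: the window must sit in the plateau
  set.seed(31)
  trend <- tidyr::expand_grid(subject_id = paste0("s", 1:8), session = 1:12) |>
    dplyr::mutate(score = ifelse(session <= 6, 15 * session, 90) +
                    rnorm(dplyr::n(), 0, 2))
  w <- stable_window(trend)
  expect_true(all(w >= 7))
  expect_error(stable_window(flat, k = 12), "fewer than k")
})

test_that("devaluation shifts are paired, zero-sum differences", {
  base <- fake_trials(sample(rep(paste0("P", 1:4), 25)))
  s_base <- behavior_summary(base)
  expect_equal(unlist(devaluation_shift(s_base, s_base)[, paste0("delta_P", 1:4)],
                      use.names = FALSE), rep(0, 4))
  dev <- fake_trials(c(rep("P1", 40), rep("P2", 30), rep("P3", 20), rep("P4", 10)))
  s_dev <- behavior_summary(dev)
  shift <- devaluation_shift(s_base, s_dev)
  expect_equal(unlist(shift[, paste0("delta_P", 1:4)], use.names = FALSE),
               c(15, 5, -5, -15))
  expect_equal(sum(unlist(shift[, paste0("delta_P", 1:4)])), 0, tolerance = 1e-9)
  other <- dplyr::mutate(s_dev, subject_id = "other")
  expect_error(devaluation_shift(s_base, other), "same subject")
})

test_that("one-way ANOVA matches the hand-computed textbook fixture", {
  score <- c(1, 2, 3, 2, 3, 4, 5, 6, 7)
  grp <- rep(c("a", "b", "c"), each = 3)
  a <- one_way_anova(score, grp)
  expect_equal(a$f_stat, 13)  # SSB 26 / df 2 over SSW 6 / df 6
  expect_equal(a$df_between, 2)
  expect_equal(a$df_within, 6)
  same <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$f_stat, 0)
  expect_equal(same$p_value, 1)
  # two groups: F equals the squared pooled t
  set.seed(9)
  x <- rnorm(10); y <- rnorm(12, 1)
  f2 <- one_way_anova(c(x, y), rep(c("x", "y"), c(10, 12)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(f2$f_stat, tt$statistic[["t"]]^2, tolerance = 1e-10)
  expect_equal(f2$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("Tukey HSD agrees with the reference implementation and its identities", {
  set.seed(12)
  score <- c(rnorm(8, 0), rnorm(8, 1.5), rnorm(8, 0.5))
  grp <- rep(c("uncued", "standard", "reverse"), each = 8)
  got <- tukey_hsd(score, grp)
  ref <- TukeyHSD(aov(score ~ factor(grp)))[[1]]
  # reference reports later-minus-earlier level; ours row-minus-column
  for (i in seq_len(nrow(got))) {
    key <- paste0(got$group2[i], "-", got$group1[i])
    key2 <- paste0(got$group1[i], "-", got$group2[i])
    if (key %in% rownames(ref)) {
      expect_equal(got$mean_diff[i], -ref[key, "diff"], tolerance = 1e-10)
      expect_equal(got$p_adj[i], ref[key, "p adj"], tolerance = 1e-8)
    } else {
      expect_equal(got$mean_diff[i], ref[key2, "diff"], tolerance = 1e-10)
      expect_equal(got$p_adj[i], ref[key2, "p adj"], tolerance = 1e-8)
    }
  }
  # identical groups: zero differences, p = 1
  same <- tukey_hsd(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$mean_diff, rep(0, 3))
  expect_equal(same$p_adj, rep(1, 3))
  # two groups: the adjusted p collapses to the plain two-sample p
  x <- rnorm(9); y <- rnorm(9, 1)
  two <- tukey_hsd(c(x, y), rep(c("a", "b"), each = 9))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(two$p_adj, tt$p.value, tolerance = 1e-8)
})

test_that("behavior summary composes the endpoint measures consistently", {
  set.seed(2)
  co <- small_cohort(n_subjects = 3, n_sessions = 2, seed = 61)
  s <- behavior_summary(co$trials)
  expect_equal(nrow(s), 3)
  expect_equal(rowSums(as.matrix(s[, paste0("pct_P", 1:4)])), rep(100, 3),
               tolerance = 1e-9)
  expect_equal(s$decision_score,
               (s$pct_P1 + s$pct_P2) - (s$pct_P3 + s$pct_P4))
  expect_equal(s$risk_status, classify_risk_status(s$decision_score))
})
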