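Package: rgtrl
Title: Reinforcement-Learning Models of Risky Choice on the Rat Gambling Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the rat gambling task (rGT), a four-option operant
    task trading per-trial reward size against the probability and duration
    of time-out penalties, and models trial-by-trial learning from wins and
    losses with a family of Q-learning models (asymmetric learning rates and
    four transforms of penalty duration into pellet-equivalent cost).
    Provides hierarchical Bayesian estimation with a noncentered
    parameterization, split R-hat diagnostics, WAIC model comparison,
    highest-density-interval group contrasts, posterior-predictive forward
    simulation of long-run risk preference, maximum-likelihood fitting for
    parameter recovery, and the task's behavioral endpoints (percent choice,
    decision score, risk status, premature responding, devaluation shifts)
    with one-way ANOVA and Tukey HSD comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
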