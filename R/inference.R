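#' MCMC configuration
#'
#' Sampler settings for [fit_rgt_hier()]. Defaults follow the convention of
#' four chains of 1000 retained draws after 1000 warmup iterations; if any
#' split R-hat exceeds `rhat_threshold` the warmup is doubled (up to
#' `warmup_cap`) and the fit re-run. `preset = "desk"` switches to the
#' light preset used for desk-scale simulation studies (2 chains x 500).
#'
#' @param n_chains Number of chains.
#' @param n_warmup Warmup (adaptation) iterations per chain.
#' @param n_samples Retained draws per chain.
#' @param seed Integer seed; chain `c` uses `seed + c`.
#' @param rhat_threshold Convergence threshold on split R-hat.
#' @param warmup_cap Maximum warmup after escalation.
#' @param thin Keep every `thin`-th post-warmup sweep (retained draws stay
#'   `n_samples`; sweeps run is `n_samples * thin`). Thinning buys less
#'   autocorrelated draws for a linear cost and no extra memory.
#' @param preset `"paper"` (4 chains x 1000/1000, escalation to 5000) or
#'   `"desk"` (2 chains x 500/500, thin 3, no escalation): the light
#'   preset for simulation studies, which trades full convergence
#'   certification for runtime — fits keep their `converged` flag either
#'   way.
#' @return A list of class `rgt_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_warmup = 1000, n_samples = 1000,
                        seed = 1, rhat_threshold = 1.01, warmup_cap = 5000,
                        thin = 5, preset = NULL) {
  if (!is.null(preset) && preset == "desk") {
    n_chains <- 2; n_warmup <- 500; n_samples <- 500; thin <- 3
    warmup_cap <- 500
  }
  stopifnot(n_chains >= 1, n_warmup >= 1, n_samples >= 1, thin >= 1,
            rhat_threshold > 1)
  structure(list(n_chains = n_chains, n_warmup = n_warmup,
                 n_samples = n_samples, seed = seed,
                 rhat_threshold = rhat_threshold, warmup_cap = warmup_cap,
                 thin = thin),
            class = "rgt_mcmc_config")
}

subject_data_list <- function(trials) {
  split(trials, factor(trials$subject_id, levels = unique(trials$subject_id))) |>
    purrr::map(function(d) {
      list(choice = choice_index_vec(d$choice),
           win = as.integer(d$outcome == "win"),
           pellets = as.numeric(d$pellets),
           penalty_s = as.numeric(d$penalty_s))
    })
}

prior_spec <- function(pnames) {
  list(mean = unname(vapply(pnames, function(p) 0, numeric(1))),
       sd = unname(vapply(pnames, function(p) if (p == "b") 2 else 1,
                          numeric(1))))
}

#' Hierarchical Bayesian fit of an RL model to a cohort
#'
#' Partially pools choice data across subjects: subject parameters are
#' expressed noncentered as `group_mean + group_SD * z` on the
#' unconstrained scale and mapped through the constraint transforms (probit
#' for learning rates, exp for `beta`/`m`/`r`/`mRew`, identity for `b`).
#' Priors are weakly informative: Normal(0, 1) group means (Normal(0, 2)
#' for the offset), half-Normal(0, 1) group SDs, standard-normal z. The
#' posterior is sampled by an adaptive Metropolis-within-Gibbs scheme
#' (per-subject z blocks; joint mean/SD blocks per parameter) whose step
#' sizes adapt during warmup only. Convergence is assessed with split
#' R-hat on every group- and subject-level quantity; if any exceeds the
#' threshold, warmup is doubled (to at most the cap) and the fit re-run.
#'
#' @param trials Trial-log tibble (>= 2 subjects). Only valid choices from
#'   `sessions` are used — the learning window the models target.
#' @param model Model name from [rl_models()].
#' @param config An [mcmc_config()] object.
#' @param sessions Session window to fit (default first five).
#' @return An object of class `rgt_hierfit`: posterior draws for group
#'   means/SDs and subject-level parameters (natural scale), pointwise
#'   log-likelihood draws, per-quantity split R-hat, and the config echo.
#' @export
fit_rgt_hier <- function(trials, model, config = mcmc_config(),
                         sessions = 1:5) {
  trials <- valid_choices(trials, sessions)
  dat <- subject_data_list(trials)
  if (length(dat) < 2) stop("hierarchical fitting needs >= 2 subjects", call. = FALSE)
  pnames <- model_param_names(model)
  P <- length(pnames)
  prior <- prior_spec(pnames)
  trans <- param_trans_code(pnames)
  subjects <- names(dat)
  n_points <- sum(vapply(dat, function(d) length(d$choice), integer(1)))

  warmup <- config$n_warmup
  escalation <- integer(0)
  repeat {
    chains <- purrr::map(seq_len(config$n_chains), function(ch) {
      set.seed((config$seed + ch) %% .Machine$integer.max)
      cpp_fit_chain(unname(dat), model_id_int(model), P, trans,
                    prior$mean, prior$sd, warmup, config$n_samples,
                    config$thin, 0.3)
    })
    fit <- build_hierfit(chains, model, pnames, subjects, config, warmup,
                         n_points, trials)
    escalation <- c(escalation, warmup)
    bad <- !is.na(fit$diagnostics$rhat) &
      fit$diagnostics$rhat > config$rhat_threshold
    if (!any(bad) || warmup >= config$warmup_cap || config$n_chains < 2) break
    warmup <- min(2 * warmup, config$warmup_cap)
  }
  fit$escalation <- escalation
  fit$converged <- !any(!is.na(fit$diagnostics$rhat) &
                          fit$diagnostics$rhat > config$rhat_threshold)
  if (!fit$converged)
    warning("R-hat above ", config$rhat_threshold,
            " after warmup escalation to ", warmup, call. = FALSE)
  fit
}

build_hierfit <- function(chains, model, pnames, subjects, config, warmup,
                          n_points, trials) {
  P <- length(pnames)
  S <- length(subjects)
  n <- config$n_samples
  arr <- function(key, ncol) {
    a <- array(NA_real_, c(n, length(chains), ncol))
    for (c in seq_along(chains)) a[, c, ] <- chains[[c]][[key]]
    a
  }
  mu <- arr("mu", P); sigma <- arr("sigma", P); grp <- arr("group", P)
  theta <- arr("theta", S * P)
  ll <- do.call(rbind, purrr::map(chains, "loglik"))
  dimnames(mu)[[3]] <- dimnames(sigma)[[3]] <- dimnames(grp)[[3]] <- pnames
  dimnames(theta)[[3]] <- paste(rep(subjects, each = P), pnames, sep = ".")

  diag_one <- function(a, label) {
    tibble::tibble(
      quantity = paste0(label, "[", dimnames(a)[[3]], "]"),
      rhat = vapply(seq_len(dim(a)[3]), function(k) rhat(a[, , k]), numeric(1))
    )
  }
  diagnostics <- dplyr::bind_rows(
    diag_one(mu, "group_mean"), diag_one(sigma, "group_sd"),
    diag_one(theta, "subject"))

  structure(list(
    model = model, param_names = pnames, subjects = subjects,
    group_mu = mu, group_sigma = sigma, group_natural = grp,
    subject_draws = theta, pointwise_loglik = ll,
    diagnostics = diagnostics, config = config, warmup_used = warmup,
    n_points = n_points,
    accept = mean(vapply(chains, function(x) x$accept, numeric(1))),
    trial_index = trials[, c("subject_id", "session", "trial_index")]
  ), class = "rgt_hierfit")
}

#' @export
print.rgt_hierfit <- function(x, ...) {
  cat("Hierarchical RL fit:", x$model, "model,", length(x$subjects),
      "subjects,", x$n_points, "valid trials\n")
  cat("Chains:", x$config$n_chains, "x", x$config$n_samples,
      "draws (warmup", x$warmup_used, ")\n")
  cat("Max split R-hat:", round(max(x$diagnostics$rhat, na.rm = TRUE), 4), "\n")
  invisible(x)
}

#' Posterior mean subject-level parameter estimates
#'
#' @param fit An `rgt_hierfit`.
#' @param point `"mean"` (default) or `"median"`.
#' @return Tibble: `subject_id`, `model`, one column per parameter.
#' @export
subject_estimates <- function(fit, point = c("mean", "median")) {
  point <- match.arg(point)
  f <- if (point == "mean") mean else stats::median
  th <- fit$subject_draws
  est <- apply(th, 3, f)
  P <- length(fit$param_names)
  m <- matrix(est, ncol = P, byrow = TRUE,
              dimnames = list(NULL, fit$param_names))
  tibble::tibble(subject_id = fit$subjects, model = fit$model) |>
    dplyr::bind_cols(tibble::as_tibble(m))
}

group_level_draws <- function(fit, parameter) {
  if (!parameter %in% fit$param_names)
    stop("parameter '", parameter, "' not in model '", fit$model, "'",
         call. = FALSE)
  as.numeric(fit$group_natural[, , parameter])
}

#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction factor comparing between-chain to within-chain
#' variance, computed after splitting each chain in half (so a single
#' drifting chain is also caught). Values near 1 indicate the chains agree;
#' the conventional acceptance threshold here is 1.01. Degenerate input
#' (zero within-chain variance) yields `NA` with a warning, since the
#' statistic is undefined.
#'
#' @param draws An iterations x chains matrix (>= 2 chains, >= 4 draws).
#' @return The split R-hat statistic (scalar).
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2 || nrow(draws) < 4)
    stop("rhat needs >= 2 chains of >= 4 draws", call. = FALSE)
  half <- floor(nrow(draws) / 2)
  split_chains <- cbind(draws[seq_len(half), , drop = FALSE],
                        draws[(nrow(draws) - half + 1):nrow(draws), , drop = FALSE])
  m <- ncol(split_chains); n <- nrow(split_chains)
  w <- mean(apply(split_chains, 2, var))
  if (!is.finite(w) || w == 0) {
    warning("zero within-chain variance; R-hat undefined", call. = FALSE)
    return(NA_real_)
  }
  b <- n * var(colMeans(split_chains))
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Watanabe-Akaike information criterion
#'
#' Computed from pointwise posterior log-likelihoods: for data point `i`,
#' `elpd_i = log mean_s exp(ll_si) - var_s(ll_si)`, the log pointwise
#' predictive density minus the variance complexity penalty. The total is
#' reported on the `-2 * elpd` deviance scale (lower = better predicted)
#' with a pointwise standard error.
#'
#' @param pointwise_loglik Draws x data-points matrix of log-likelihoods,
#'   or an `rgt_hierfit` (its stored matrix is used).
#' @return A list of class `rgt_waic`: `waic`, `elpd`, `p_waic`, `se`,
#'   `n_points`, and `pointwise` (per-point `-2 * elpd_i`).
#' @export
waic <- function(pointwise_loglik) {
  if (inherits(pointwise_loglik, "rgt_hierfit"))
    pointwise_loglik <- pointwise_loglik$pointwise_loglik
  ll <- as.matrix(pointwise_loglik)
  if (nrow(ll) < 2) stop("waic needs >= 2 posterior draws", call. = FALSE)
  if (any(!is.finite(ll))) stop("non-finite log-likelihood entries", call. = FALSE)
  mx <- apply(ll, 2, max)
  lpd <- mx + log(colMeans(exp(sweep(ll, 2, mx, `-`))))
  pw_var <- apply(ll, 2, var)
  elpd_i <- lpd - pw_var
  pointwise <- -2 * elpd_i
  structure(list(elpd = sum(elpd_i), p_waic = sum(pw_var),
                 waic = sum(pointwise),
                 se = sqrt(length(elpd_i) * var(pointwise)),
                 n_points = length(elpd_i), pointwise = pointwise),
            class = "rgt_waic")
}

#' @export
print.rgt_waic <- function(x, ...) {
  cat("WAIC:", round(x$waic, 1), " (elpd", round(x$elpd, 1), ", p_waic",
      round(x$p_waic, 1), ", SE", round(x$se, 1), ",", x$n_points, "points)\n")
  invisible(x)
}

#' Paired WAIC difference between two models
#'
#' Reference-minus-model difference computed pointwise over the shared data
#' points (positive = `fit` predicts better than `reference`), with the SEM
#' of the paired pointwise differences — the comparison convention for
#' plotting each model against the basic delta-rule baseline.
#'
#' @param fit,reference `rgt_waic` objects (or `rgt_hierfit`s, converted
#'   via [waic()]) fit to the same data points.
#' @return Tibble: `delta_waic` (reference WAIC - model WAIC), `se`
#'   (SEM of the difference), `n_points`.
#' @export
waic_difference <- function(fit, reference) {
  if (inherits(fit, "rgt_hierfit")) fit <- waic(fit)
  if (inherits(reference, "rgt_hierfit")) reference <- waic(reference)
  if (fit$n_points != reference$n_points)
    stop("WAIC comparison requires the same data points", call. = FALSE)
  d <- reference$pointwise - fit$pointwise
  tibble::tibble(delta_waic = sum(d),
                 se = sqrt(length(d) * var(d)),
                 n_points = length(d))
}

mle_bounds <- function(pnames) {
  lower <- c(beta = 1e-6, eta_plus = 1e-6, eta_minus = 1e-6,
             m = 1e-6, b = -20, r = 1e-6, mRew = 1e-6)[pnames]
  upper <- c(beta = 30, eta_plus = 1 - 1e-6, eta_minus = 1 - 1e-6,
             m = 2, b = 20, r = 3, mRew = 5)[pnames]
  list(lower = unname(lower), upper = unname(upper))
}

#' Maximum-likelihood fit per subject
#'
#' Multi-start bounded optimization (L-BFGS-B over Latin-hypercube starts)
#' of the sequential choice log-likelihood, subject by subject. A fast,
#' non-pooled counterpart to [fit_rgt_hier()] used for parameter-recovery
#' checks and as an independent cross-check of the posterior.
#'
#' @param trials Trial-log tibble.
#' @param model Model name.
#' @param n_starts Number of Latin-hypercube starting points.
#' @param bounds Optional list with `lower`/`upper` vectors (natural scale)
#'   overriding the defaults.
#' @param seed Seed for the start design.
#' @param sessions Session window (default first five).
#' @return Tibble: one row per subject with the fitted parameters,
#'   `loglik`, `n_trials`, `converged`, and `low_information` (flagged when
#'   too few trials constrain the likelihood).
#' @export
fit_rgt_mle <- function(trials, model, n_starts = 10, bounds = NULL,
                        seed = 1, sessions = 1:5) {
  trials <- valid_choices(trials, sessions)
  pnames <- model_param_names(model)
  P <- length(pnames)
  bd <- if (is.null(bounds)) mle_bounds(pnames) else bounds
  set.seed(seed %% .Machine$integer.max)
  starts <- lhs::randomLHS(n_starts, P)
  starts <- sweep(starts, 2, bd$upper - bd$lower, `*`)
  starts <- sweep(starts, 2, bd$lower, `+`)
  # plus one neutral start at each extra parameter's nesting value, so a
  # richer model always explores the region of the model it nests
  neutral <- c(beta = 1, eta_plus = 0.1, eta_minus = 0.1, m = 0.1, b = 0,
               r = 1, mRew = 1)[pnames]
  starts <- rbind(starts, unname(neutral))
  n_starts <- n_starts + 1L
  mid <- model_id_int(model)

  dat <- subject_data_list(trials)
  purrr::imap(dat, function(d, sid) {
    negll <- function(x) {
      -sum(cpp_pointwise_loglik(d$choice, d$win, d$pellets, d$penalty_s,
                                mid, x))
    }
    fits <- purrr::map(seq_len(n_starts), function(i) {
      tryCatch(optim(starts[i, ], negll, method = "L-BFGS-B",
                     lower = bd$lower, upper = bd$upper,
                     control = list(maxit = 1000, factr = 1e4)),
               error = function(e) NULL)
    })
    fits <- purrr::compact(fits)
    if (!length(fits)) {
      return(tibble::tibble(subject_id = sid, model = model,
                            loglik = NA_real_, n_trials = length(d$choice),
                            converged = FALSE, low_information = TRUE))
    }
    best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
    est <- setNames(as.list(best$par), pnames)
    tibble::tibble(subject_id = sid, model = model) |>
      dplyr::bind_cols(tibble::as_tibble(est)) |>
      dplyr::mutate(loglik = -best$value, n_trials = length(d$choice),
                    converged = best$convergence == 0,
                    low_information = length(d$choice) < 10 * P)
  }) |> dplyr::bind_rows()
}
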