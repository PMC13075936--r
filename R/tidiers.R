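#' Tidy a hierarchical fit's group-level posterior
#'
#' @param x An `rgt_hierfit`.
#' @param prob HDI mass for the interval columns.
#' @param ... Unused.
#' @return Tibble: one row per parameter with posterior mean, SD, HDI
#'   bounds (group-level location on the natural scale) and its split
#'   R-hat.
#' @export
tidy.rgt_hierfit <- function(x, prob = 0.95, ...) {
  purrr::map(x$param_names, function(p) {
    d <- as.numeric(x$group_natural[, , p])
    h <- hdi(d, prob)
    tibble::tibble(parameter = p, estimate = mean(d), std_error = sd(d),
                   hdi_low = h[["lower"]], hdi_high = h[["upper"]],
                   rhat = x$diagnostics$rhat[
                     x$diagnostics$quantity == paste0("group_mean[", p, "]")])
  }) |> dplyr::bind_rows()
}

#' One-line summary of a hierarchical fit
#'
#' @param x An `rgt_hierfit`.
#' @param ... Unused.
#' @return One-row tibble: model, subjects, trials, draws, max R-hat,
#'   convergence flag, warmup used, mean acceptance.
#' @export
glance.rgt_hierfit <- function(x, ...) {
  tibble::tibble(model = x$model, n_subjects = length(x$subjects),
                 n_points = x$n_points,
                 n_draws = dim(x$group_mu)[1] * dim(x$group_mu)[2],
                 max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
                 converged = isTRUE(x$converged),
                 warmup = x$warmup_used, accept = x$accept)
}

#' @rdname waic
#' @param x An `rgt_waic`.
#' @param ... Unused.
#' @export
tidy.rgt_waic <- function(x, ...) {
  tibble::tibble(waic = x$waic, elpd = x$elpd, p_waic = x$p_waic,
                 se = x$se, n_points = x$n_points)
}

#' Compare several fitted models by WAIC
#'
#' @param fits Named list of `rgt_hierfit` or `rgt_waic` objects fit to the
#'   same data.
#' @param reference Name of the baseline model for the difference columns
#'   (default `"basic"` when present, else the worst model).
#' @return Tibble sorted best-first with WAIC, and paired
#'   reference-minus-model differences with their SEM.
#' @export
compare_waic <- function(fits, reference = NULL) {
  ws <- purrr::map(fits, function(f) if (inherits(f, "rgt_hierfit")) waic(f) else f)
  tab <- purrr::imap(ws, function(w, nm) {
    dplyr::mutate(tidy(w), model = nm, .before = 1)
  }) |> dplyr::bind_rows()
  if (is.null(reference))
    reference <- if ("basic" %in% tab$model) "basic" else tab$model[which.max(tab$waic)]
  ref <- ws[[reference]]
  diffs <- purrr::map(ws, function(w) waic_difference(w, ref)) |>
    dplyr::bind_rows()
  out <- dplyr::mutate(tab, delta_waic = diffs$delta_waic,
                       delta_se = diffs$se, reference = reference)
  structure(dplyr::arrange(out, .data$waic), class = c("rgt_waic_comparison",
                                                       class(out)))
}
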