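#' Plot group-level posterior densities
#'
#' @param object An `rgt_hierfit`.
#' @param ... Unused.
#' @return A ggplot: one density panel per parameter (natural scale).
#' @export
autoplot.rgt_hierfit <- function(object, ...) {
  d <- purrr::map(object$param_names, function(p) {
    tibble::tibble(parameter = p,
                   value = as.numeric(object$group_natural[, , p]))
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey70") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "group-level posterior (natural scale)", y = "density",
                  title = paste(object$model, "model")) +
    ggplot2::theme_minimal()
}

#' Plot a WAIC model comparison
#'
#' @param object Output of [compare_waic()].
#' @param ... Unused.
#' @return A ggplot of reference-minus-model WAIC differences with SEM
#'   error bars (larger = better than the reference).
#' @export
autoplot.rgt_waic_comparison <- function(object, ...) {
  d <- dplyr::filter(object, .data$model != .data$reference)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$delta_waic)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$delta_waic - .data$delta_se,
                                        ymax = .data$delta_waic + .data$delta_se),
                           width = 0.2) +
    ggplot2::labs(y = paste0("WAIC(", object$reference[1], ") - WAIC(model)"),
                  x = NULL) +
    ggplot2::theme_minimal()
}

#' Choice trajectories across sessions
#'
#' @param trials Trial-log tibble.
#' @return A ggplot of mean percent choice of each option by session,
#'   faceted by task variant when present.
#' @export
plot_choice_curves <- function(trials) {
  keys <- intersect(c("task_variant"), names(trials))
  d <- trials |>
    dplyr::filter(.data$outcome %in% c("win", "loss")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "subject_id", "session")))) |>
    dplyr::summarise(pct = list(choice_percentages_vec(.data$choice)),
                     .groups = "drop") |>
    tidyr::unnest_wider("pct") |>
    tidyr::pivot_longer(dplyr::all_of(paste0("P", 1:4)),
                        names_to = "option", values_to = "pct_choice") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "session", "option")))) |>
    dplyr::summarise(pct_choice = mean(.data$pct_choice), .groups = "drop")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$session, y = .data$pct_choice,
                                       colour = .data$option)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "% choice", x = "session") +
    ggplot2::theme_minimal()
  if (length(keys)) p <- p + ggplot2::facet_wrap(~task_variant)
  p
}
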