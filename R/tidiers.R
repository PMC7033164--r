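## broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a fitted model
#'
#' One row per data split with the raw-unit accuracy metrics.
#'
#' @param x A `psobp_fit`.
#' @param ... Unused.
#' @return A tibble: `split`, `mse`, `rmse`, `mae`, `mre`, `r2`, `rmse_norm`, `n`.
#' @export
tidy.psobp_fit <- function(x, ...) {
  x$metrics[, c("split", "mse", "rmse", "mae", "mre", "r2", "rmse_norm", "n")]
}

#' Glance at a fitted model
#'
#' @param x A `psobp_fit`.
#' @param ... Unused.
#' @return A one-row tibble summarising the fit (validation metrics, epochs,
#'   convergence, architecture).
#' @export
glance.psobp_fit <- function(x, ...) {
  val <- x$metrics[x$metrics$split == "validation", ]
  tibble::tibble(
    method = x$method, target = x$target,
    r2 = val$r2, rmse = val$rmse, mae = val$mae,
    epochs_used = x$train_result$epochs_used,
    converged = x$train_result$converged,
    hidden_nodes = x$arch$L,
    pso_iterations = if (is.null(x$pso_result)) NA_integer_ else
      x$pso_result$iterations_used)
}

#' Tidy a BP vs PSO-BP comparison
#'
#' @param x A `psobp_comparison`.
#' @param ... Unused.
#' @return The per-seed tibble.
#' @export
tidy.psobp_comparison <- function(x, ...) x$per_seed

#' @rdname tidy.psobp_comparison
#' @export
glance.psobp_comparison <- function(x, ...) {
  tidyr::pivot_wider(x$summary |>
                       tidyr::pivot_longer(-"method", names_to = "metric"),
                     names_from = c("metric", "method"), values_from = "value")
}

#' Tidy the fluorescence-model battery
#'
#' @param x A `psobp_fluor_models`.
#' @param ... Unused.
#' @return The report tibble (one row per model per split).
#' @export
tidy.psobp_fluor_models <- function(x, ...) x$report

#' Diagnostic plot of a fitted model
#'
#' Observed-vs-predicted scatter by split, alongside the training convergence
#' trace (log10 MSE per epoch).
#'
#' @param object A `psobp_fit`.
#' @param which `"predictions"` or `"trace"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psobp_fit <- function(object, which = c("predictions", "trace"), ...) {
  which <- match.arg(which)
  if (which == "predictions") {
    ggplot2::ggplot(object$predictions,
                    ggplot2::aes(x = .data$observed, y = .data$predicted,
                                 colour = .data$split)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::geom_point(alpha = 0.5, size = 0.8) +
      ggplot2::labs(x = paste("observed", object$target),
                    y = paste("predicted", object$target)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$train_result$trace,
                    ggplot2::aes(x = .data$epoch, y = .data$mse)) +
      ggplot2::geom_line() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "epoch", y = "training MSE (normalized)") +
      ggplot2::theme_minimal()
  }
}

#' Convergence comparison plot
#'
#' Per-seed epochs-to-goal and validation MSE by method.
#'
#' @param object A `psobp_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psobp_comparison <- function(object, ...) {
  d <- object$per_seed |>
    dplyr::mutate(epochs_to_goal = ifelse(is.finite(.data$epochs_to_goal),
                                          .data$epochs_to_goal, NA)) |>
    tidyr::pivot_longer(c("epochs_to_goal", "val_mse"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::theme_minimal()
}
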