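#' Plot a simulated trajectory
#'
#' @param object An `"ews_trajectory"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ews_trajectory <- function(object, ...) {
  a <- attributes(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$x)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "t", y = "X(t)",
      title = sprintf("%s model, alpha = %g, gamma_n = %g (%s scheme)",
                      a$model, a$alpha, a$gamma_n, a$scheme)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an early-warning indicator series
#'
#' Rolling series are drawn against the bifurcation parameter `k` (reversed
#' axis: the bifurcation is approached rightward); expanding series against
#' the anchor step.
#'
#' @param object An `"ews_series"`.
#' @param indicator Column to draw (default `"gamma_hat"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ews_series <- function(object, indicator = "gamma_hat", ...) {
  mode <- attr(object, "mode")
  if (identical(mode, "rolling")) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data[[indicator]])) +
      ggplot2::geom_line() +
      ggplot2::scale_x_reverse() +
      ggplot2::labs(x = "k (toward bifurcation)", y = indicator) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$anchor, y = .data[[indicator]])) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "steps", y = indicator) +
      ggplot2::theme_minimal()
  }
}

#' Equilibrium results against theory (log-log)
#'
#' Replicate-level fitted scales and their mean per `k`, with the
#' closed-form stationary scale overlaid, per `alpha`.
#'
#' @param results Output of [run_equilibrium()].
#' @return A ggplot, faceted by `alpha`.
#' @export
plot_equilibrium <- function(results) {
  summ <- summarise_equilibrium(results)
  ggplot2::ggplot(dplyr::filter(results, !is.na(.data$gamma_hat)),
                  ggplot2::aes(x = .data$k, y = .data$gamma_hat)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_point(data = summ, ggplot2::aes(y = .data$mean_gamma),
                        color = "red", size = 2) +
    ggplot2::geom_line(data = summ, ggplot2::aes(y = .data$theory_gamma_x),
                       color = "orange") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~alpha, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "k", y = "fitted gamma_X") +
    ggplot2::theme_minimal()
}

#' Non-equilibrium ramp series with theory curve
#'
#' Thin lines per trajectory (smoothed), bold mean, dashed theory.
#'
#' @param results Output of [run_nonequilibrium()].
#' @return A ggplot, faceted by `alpha`.
#' @export
plot_nonequilibrium <- function(results) {
  summ <- summarise_nonequilibrium(results)
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$k, y = .data$gamma_smooth,
                               group = .data$traj)) +
    ggplot2::geom_line(alpha = 0.3, linewidth = 0.2) +
    ggplot2::geom_line(data = summ,
                       ggplot2::aes(y = .data$mean_gamma_smooth, group = NULL),
                       linewidth = 0.9) +
    ggplot2::geom_line(data = summ,
                       ggplot2::aes(y = .data$theory_gamma_x, group = NULL),
                       linetype = "dashed", color = "orange") +
    ggplot2::scale_x_reverse() +
    ggplot2::facet_wrap(~alpha, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "k (toward bifurcation)", y = "smoothed gamma_X") +
    ggplot2::theme_minimal()
}

#' Running variance versus running fitted scale
#'
#' The false-positive demonstration: per-trajectory running statistics
#' (thin) and their cross-trajectory mean (bold), log y-axis, faceted by
#' indicator and `alpha`.
#'
#' @param results Output of [run_divergence()].
#' @return A ggplot.
#' @export
plot_divergence <- function(results) {
  long <- tidyr::pivot_longer(results, c("variance_hat", "gamma_hat"),
                              names_to = "indicator")
  mean_ser <- long |>
    dplyr::group_by(.data$alpha, .data$indicator, .data$anchor) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$anchor, y = .data$value,
                                     group = .data$traj)) +
    ggplot2::geom_line(alpha = 0.15, linewidth = 0.2) +
    ggplot2::geom_line(data = mean_ser, ggplot2::aes(group = NULL),
                       linewidth = 0.9, color = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(indicator ~ alpha, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "steps", y = "running statistic") +
    ggplot2::theme_minimal()
}
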