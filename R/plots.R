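#' Plot a distribution-volume curve
#'
#' Vd% against time with the peak and, when defined, the half-maximum
#' crossing marked.
#'
#' @param object A `vd_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vd_curve <- function(object, ...) {
  df <- tidy(object)
  m <- glance(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s / 60, y = .data$vd_pct)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_vline(xintercept = m$t_max_s / 60, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Time post-injection (min)",
                  y = "Vd (% of reference volume)",
                  title = sprintf("Vd-max %.3g%% at %.0f min", m$vd_max_pct,
                                  m$t_max_s / 60)) +
    ggplot2::theme_minimal()
  if (isTRUE(m$t_half_defined)) {
    p <- p + ggplot2::geom_vline(xintercept = (m$t_max_s + m$t_half_s) / 60,
                                 linetype = "dotted", colour = "firebrick")
  }
  p
}

#' Plot observed against fitted concentrations of a point-source fit
#'
#' @param object A `point_source_fit`.
#' @param max_points Subsample cap for large observation sets.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.point_source_fit <- function(object, max_points = 5000L, ...) {
  df <- object$data
  if (nrow(df) > max_points) {
    df <- df[seq(1L, nrow(df), length.out = max_points), ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$conc)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "firebrick") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Fitted concentration (mol/mm^3)",
                  y = "Observed concentration (mol/mm^3)",
                  title = sprintf("Point-source fit: D* = %.3g mm^2/s, k' = %.3g 1/s",
                                  object$d_eff, object$k_clear)) +
    ggplot2::theme_minimal()
}

#' Group-wise dot plot of an estimated parameter
#'
#' @param results Per-animal results tibble (e.g. from [analyze_cohort()] or
#'   an empirical [draw_cohort()]).
#' @param parameter Column name (unquoted) to plot.
#' @return A ggplot.
#' @export
plot_group_parameter <- function(results, parameter) {
  parameter <- rlang::enquo(parameter)
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$group, y = !!parameter)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.7, colour = "steelblue") +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "black") +
    ggplot2::theme_minimal()
}
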