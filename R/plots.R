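#' Plot methods for fitted objects
#'
#' `autoplot()` methods returning ggplot objects: the double-reciprocal
#' line for an isotherm fit, the sigmoid with its midpoint for a melt fit,
#' both linearised rate laws for an order selection, and the Stern-Volmer
#' plus double-log panels for a quenching analysis. [plot_scatchard()] and
#' [plot_hill()] draw the cooperativity diagnostics from binding points.
#'
#' @param object A fitted object.
#' @param series The series the object was fitted to (isotherm, kinetics
#'   and quenching methods re-plot the underlying data).
#' @param ... Unused.
#' @return A ggplot object.
#' @name bindspectra-plots
NULL

#' @rdname bindspectra-plots
#' @exportS3Method ggplot2::autoplot
autoplot.isotherm_fit <- function(object, series, ...) {
  stopifnot(inherits(series, "titration_series"))
  A0 <- object$endpoints$A0
  df <- dplyr::filter(
    tibble(x = 1 / series$ligand_total, y = 1 / (series$signal - A0)),
    is.finite(.data$x), is.finite(.data$y)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$fit$slope,
                         intercept = object$fit$intercept,
                         linetype = 2) +
    ggplot2::labs(
      x = expression(1 / "[L]" ~ (M^-1)),
      y = expression(1 / (A - A[0]) ~ (AU^-1)),
      title = sprintf("Double-reciprocal fit: K_b = %.3g M^-1 (R^2 = %.4f)",
                      object$K_b, object$fit$r_squared)
    )
}

#' @rdname bindspectra-plots
#' @param trace The [melt_trace()] the melt fit used.
#' @exportS3Method ggplot2::autoplot
autoplot.melt_fit <- function(object, trace, ...) {
  stopifnot(inherits(trace, "melt_trace"))
  grid <- seq(min(trace$temperature_K), max(trace$temperature_K),
              length.out = 200)
  pre <- object$baselines[["pre"]]
  post <- object$baselines[["post"]]
  curve <- tibble(
    temperature_K = grid,
    signal = pre + (post - pre) / (1 + exp((object$T_m - grid) / object$width))
  )
  ggplot2::ggplot(trace,
                  ggplot2::aes(x = .data$temperature_K, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$T_m, linetype = 2) +
    ggplot2::labs(x = "Temperature (K)", y = "Signal (AU)",
                  title = sprintf("Two-state melt: T_m = %.2f K (%.1f C)",
                                  object$T_m, object$T_m_C))
}

#' @rdname bindspectra-plots
#' @exportS3Method ggplot2::autoplot
autoplot.order_selection <- function(object, series, ...) {
  stopifnot(inherits(series, "kinetic_trace"))
  A_inf <- attr(series, "A_inf")
  gap <- abs(A_inf - series$signal)
  keep <- gap > 0
  df <- tidyr::pivot_longer(
    tibble(time = series$time[keep],
           `first order: ln(A_inf - A)` = log(gap[keep]),
           `second order: 1/(A_inf - A)` = 1 / gap[keep]),
    cols = -"time", names_to = "transform", values_to = "y"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$y)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::facet_wrap(~transform, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Transformed signal",
                  title = sprintf("Order selection: %s order (margin %.1e)",
                                  object$chosen, object$margin))
}

#' @rdname bindspectra-plots
#' @exportS3Method ggplot2::autoplot
autoplot.quench_fit <- function(object, series, ...) {
  stopifnot(inherits(series, "quench_series"))
  F0 <- attr(series, "F0")
  df <- tibble(Q = series$Q, y = F0 / series$F_signal)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$Q, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$fits$sv$slope,
                         intercept = object$fits$sv$intercept,
                         linetype = 2) +
    ggplot2::labs(x = "[Q] (M)", y = expression(F[0] / F),
                  title = sprintf("Stern-Volmer: K_sv = %.3g M^-1 (%s)",
                                  object$K_sv, object$mechanism))
}

#' @rdname bindspectra-plots
#' @param points A data frame with `nu` and `L_free` columns.
#' @param result Optional [scatchard()] / [hill_fit()] result for the
#'   annotation.
#' @export
plot_scatchard <- function(points, result = NULL) {
  result <- result %||% scatchard(points)
  ggplot2::ggplot(result$curve,
                  ggplot2::aes(x = .data$nu, y = .data$nu_over_L)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = expression(nu),
                  y = expression(nu / "[L]"[f] ~ (M^-1)),
                  title = paste("Scatchard plot:",
                                sub("_", "-", result$classification),
                                "cooperativity"))
}

#' @rdname bindspectra-plots
#' @param g Sites per protein (when `result` is not supplied).
#' @export
plot_hill <- function(points, g = 1, result = NULL) {
  result <- result %||% hill_fit(points, g = g)
  g <- result$g
  keep <- points$nu > 0 & points$nu < g & points$L_free > 0
  df <- tibble(x = log(points$L_free[keep]),
               y = log(points$nu[keep] / (g - points$nu[keep])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = result$fit$slope,
                         intercept = result$fit$intercept, linetype = 2) +
    ggplot2::labs(x = expression(ln ~ "[L]"[f]),
                  y = expression(ln ~ (nu / (g - nu))),
                  title = sprintf("Hill plot: n_H = %.2f, K_H = %.3g",
                                  result$n_H, result$K_H))
}
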