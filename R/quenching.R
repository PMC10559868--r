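#' Stern-Volmer quenching fit
#'
#' Fits the Stern-Volmer relation
#' \deqn{F_0 / F = 1 + K_{sv} [Q]}
#' by OLS of \eqn{F_0/F} on quencher concentration. Real series often
#' curve upward at high quencher (combined static and dynamic quenching),
#' so by default the fit is restricted to the low-concentration linear
#' region: the window grows from the lowest concentrations for as long as
#' the running fit keeps \eqn{R^2 \ge} `linear_r2` (always at least 3
#' points). An intercept far from 1 (`|intercept - 1| > 0.1`) triggers a
#' curvature warning.
#'
#' @param series A [quench_series()].
#' @param linear_region Optional integer indices of the points to fit;
#'   overrides the automatic window.
#' @param linear_r2 Running-\eqn{R^2} threshold for the automatic linear
#'   window (default 0.99).
#' @return A list of class `sv_fit`: `K_sv` (M^-1), `fit` (a
#'   [fit_line()]), `n_points_used`, `curvature_warning` (logical).
#' @export
stern_volmer_fit <- function(series, linear_region = NULL,
                             linear_r2 = 0.99) {
  stopifnot(inherits(series, "quench_series"))
  F0 <- attr(series, "F0")
  y_all <- F0 / series$F_signal
  Q_all <- series$Q
  rising <- stats::coefficients(lm(y_all ~ Q_all))[2]
  if (rising < 0 && min(y_all) < 1 - 0.02) {
    abort("Fluorescence increases with quencher concentration: not a quenching series.",
          class = "bindspectra_error")
  }
  idx <- linear_region %||% linear_window(Q_all, y_all, linear_r2)
  if (length(idx) < 3) {
    abort("Need >= 3 points in the fitted region.",
          class = "bindspectra_error")
  }
  fit <- fit_line(Q_all[idx], y_all[idx])
  curvature <- abs(fit$intercept - 1) > 0.1
  if (curvature) {
    warn(sprintf(
      "Stern-Volmer intercept %.3f deviates from 1: upward curvature (combined static/dynamic quenching) likely.",
      fit$intercept
    ))
  }
  structure(
    list(
      K_sv = fit$slope,
      fit = fit,
      n_points_used = length(idx),
      region = idx,
      curvature_warning = curvature
    ),
    class = "sv_fit"
  )
}

## Expanding low-concentration window: start from the smallest 3 points and
## extend while the running OLS keeps r_squared >= threshold.
linear_window <- function(Q, y, r2_min) {
  n <- length(Q)
  if (n <= 3) return(seq_len(n))
  best <- 3L
  for (m in 4:n) {
    if (fit_line(Q[1:m], y[1:m])$r_squared >= r2_min) best <- m else break
  }
  seq_len(best)
}

#' Quenching mechanism from the bimolecular quenching constant
#'
#' Converts the Stern-Volmer constant into the bimolecular quenching rate
#' constant \eqn{k_q = K_{sv}/\tau_0} and classifies the mechanism:
#' \eqn{k_q} strictly above the diffusion-controlled limit
#' (2e10 M^-1 s^-1) cannot arise from collisional encounters and
#' indicates static (ground-state complex) quenching.
#'
#' @param K_sv Stern-Volmer constant, M^-1.
#' @param tau0 Unquenched fluorophore lifetime, s (> 0; default 1e-8).
#' @return A tibble with one row: `k_q` (M^-1 s^-1) and `mechanism`
#'   (`"static"` or `"dynamic"`).
#' @examples
#' quenching_mechanism(1e4, 1e-8) # k_q = 1e12 -> static
#' @export
quenching_mechanism <- function(K_sv, tau0 = 1e-8) {
  if (tau0 <= 0) {
    abort("`tau0` must be positive.", class = "bindspectra_error")
  }
  k_q <- K_sv / tau0
  tibble(
    k_q = k_q,
    mechanism = ifelse(k_q > 2e10, "static", "dynamic")
  )
}

#' Double-logarithmic binding fit from quenching data
#'
#' For static quenching the fraction of occupied fluorophores gives
#' \deqn{\log_{10}\frac{F_0 - F}{F} = \log_{10} K_b + n \log_{10} [Q],}
#' so the slope of the double-log plot estimates the apparent number of
#' binding sites `n` and the intercept estimates \eqn{\log_{10} K_b}.
#' Points with \eqn{F \ge F_0} (no quenching yet) or \eqn{[Q] = 0} are
#' excluded.
#'
#' @param series A [quench_series()].
#' @return A list of class `doublelog_fit`: `K_b` (M^-1), `n_sites`,
#'   `fit` (a [fit_line()] on the log10 axes), `n_points_used`.
#' @export
double_log_fit <- function(series) {
  stopifnot(inherits(series, "quench_series"))
  F0 <- attr(series, "F0")
  keep <- series$Q > 0 & series$F_signal < F0
  n_dropped <- sum(!keep & series$Q > 0)
  if (n_dropped > 0) {
    warn(sprintf("%d point(s) with F >= F0 excluded from the double-log fit.",
                 n_dropped))
  }
  if (sum(keep) < 3) {
    abort("Fewer than 3 admissible points with Q > 0 and F < F0.",
          class = "bindspectra_error")
  }
  x <- log10(series$Q[keep])
  y <- log10((F0 - series$F_signal[keep]) / series$F_signal[keep])
  fit <- fit_line(x, y)
  structure(
    list(
      K_b = 10^fit$intercept,
      n_sites = fit$slope,
      fit = fit,
      n_points_used = sum(keep)
    ),
    class = "doublelog_fit"
  )
}

#' Full fluorescence-quenching analysis
#'
#' Chains [stern_volmer_fit()], [quenching_mechanism()] and
#' [double_log_fit()] on one series: the Stern-Volmer constant and
#' bimolecular quenching constant with the static/dynamic verdict, and the
#' double-log binding constant and site number.
#'
#' @inheritParams stern_volmer_fit
#' @param series_T2 Optional second [quench_series()] at a higher
#'   temperature; if supplied, a falling Stern-Volmer constant with rising
#'   temperature is reported as corroborating static quenching.
#' @return An object of class `quench_fit`: list with `K_sv`, `k_q`,
#'   `mechanism`, `K_b_doublelog`, `n_sites`, `fits` (list of `sv` and
#'   `dl` [fit_line()]s), `temperature_corroboration` (or `NA`).
#' @export
analyze_quenching <- function(series, linear_region = NULL,
                              series_T2 = NULL) {
  sv <- stern_volmer_fit(series, linear_region = linear_region)
  mech <- quenching_mechanism(sv$K_sv, attr(series, "tau0"))
  dl <- double_log_fit(series)
  corroboration <- NA_character_
  if (!is.null(series_T2)) {
    sv2 <- stern_volmer_fit(series_T2, linear_region = linear_region)
    corroboration <- if (sv2$K_sv < sv$K_sv) "static_corroborated"
    else "dynamic_suggested"
  }
  structure(
    list(
      K_sv = sv$K_sv,
      k_q = mech$k_q,
      mechanism = mech$mechanism,
      K_b_doublelog = dl$K_b,
      n_sites = dl$n_sites,
      fits = list(sv = sv$fit, dl = dl$fit),
      curvature_warning = sv$curvature_warning,
      temperature_corroboration = corroboration
    ),
    class = "quench_fit"
  )
}

#' @export
print.quench_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<quench_fit> K_sv = %.4g M^-1, k_q = %.4g M^-1 s^-1 -> %s quenching\n",
           "  double-log: K_b = %.4g M^-1, n = %.3g\n"),
    x$K_sv, x$k_q, x$mechanism, x$K_b_doublelog, x$n_sites
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.quench_fit <- function(x, ...) {
  tibble(
    term = c("K_sv", "k_q", "K_b", "n"),
    estimate = c(x$K_sv, x$k_q, x$K_b_doublelog, x$n_sites),
    unit = c("M^-1", "M^-1 s^-1", "M^-1", "dimensionless")
  )
}

#' @exportS3Method generics::glance
glance.quench_fit <- function(x, ...) {
  tibble(
    K_sv = x$K_sv, k_q = x$k_q, mechanism = x$mechanism,
    K_b = x$K_b_doublelog, n_sites = x$n_sites,
    sv_r.squared = x$fits$sv$r_squared, dl_r.squared = x$fits$dl$r_squared
  )
}
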