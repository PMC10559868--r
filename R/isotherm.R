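#' Estimate the binding constant by the double-reciprocal linearisation
#'
#' The workhorse of the UV-Vis titration analysis. For a 1:1 (single-set)
#' association the measured signal obeys
#' \deqn{\frac{1}{A - A_0} = \frac{1}{A_\infty - A_0} +
#'   \frac{1}{K_b (A_\infty - A_0)} \cdot \frac{1}{[L]},}
#' so regressing \eqn{1/(A - A_0)} on \eqn{1/[L]} gives
#' \eqn{K_b = \mathrm{intercept}/\mathrm{slope}} and
#' \eqn{A_\infty = A_0 + 1/\mathrm{intercept}}.
#'
#' The linearised (unweighted OLS) estimate is the primary output, matching
#' the conventional plot; a direct nonlinear fit of the underlying
#' hyperbola is run alongside as a cross-check and reported as
#' `K_b_direct`. Points too close to the free-protein signal
#' (`|A - A0| < 3 * noise_floor`) are excluded before taking reciprocals,
#' which otherwise amplify noise without bound.
#'
#' @param series A [titration_series()].
#' @param A0 Signal of the free protein. Defaults to the reading at zero
#'   ligand when the series contains one; otherwise it must be supplied.
#' @param noise_floor Estimated per-point signal noise (AU). `NULL`
#'   (default) estimates it from the residuals of the direct hyperbola
#'   fit; `0` disables the exclusion.
#'
#' @return An object of class `isotherm_fit`: a list with `K_b` (M^-1),
#'   `endpoints` ([endpoint_pair()], `A_inf` estimated from the intercept),
#'   `L_half` (M, with attribute `extrapolated`), `fit` (the [fit_line()]
#'   result on the reciprocal axes), `K_b_direct`, `temperature` (K) and
#'   the points used/excluded.
#'
#' @examples
#' p <- binding_parameters(K_b = 5000)
#' s <- gen_uv_titration(seed = 1, params = p, sigma = 0)
#' double_reciprocal_fit(s)
#' @export
double_reciprocal_fit <- function(series, A0 = NULL, noise_floor = NULL) {
  stopifnot(inherits(series, "titration_series"))
  L <- series$ligand_total
  A <- series$signal
  if (is.null(A0)) {
    if (L[1] == 0) {
      A0 <- A[1]
    } else {
      abort("Series has no zero-ligand point; supply `A0` explicitly.",
            class = "bindspectra_error")
    }
  }
  titr <- L > 0
  L <- L[titr]
  A <- A[titr]

  direct <- direct_hyperbola_fit(L, A, A0)
  if (is.null(noise_floor)) {
    noise_floor <- direct$resid_sd %||% 0
  }

  keep <- abs(A - A0) >= 3 * noise_floor & A != A0
  if (sum(keep) < 3 && sum(A != A0) >= 3) {
    # fall back rather than fit through fewer than 3 points
    keep <- A != A0
  }
  excluded <- tibble(ligand_total = L[!keep], signal = A[!keep])
  if (sum(keep) < 3) {
    abort("Fewer than 3 points with signal distinct from A0.",
          class = "bindspectra_error")
  }
  x <- 1 / L[keep]
  y <- 1 / (A[keep] - A0)
  fit <- fit_line(x, y)
  K_b <- fit$intercept / fit$slope
  if (!is.finite(K_b) || K_b <= 0) {
    abort(sprintf(
      "Double-reciprocal fit gave non-positive K_b (%.3g): data do not show saturable binding.",
      K_b
    ), class = "bindspectra_error_nonsaturating")
  }
  A_inf <- A0 + 1 / fit$intercept
  endpoints <- endpoint_pair(A0, A_inf)
  L_half <- half_saturation(series, endpoints)
  structure(
    list(
      K_b = K_b,
      K_b_direct = direct$K_b,
      endpoints = endpoints,
      L_half = as.numeric(L_half),
      L_half_extrapolated = isTRUE(attr(L_half, "extrapolated")),
      fit = fit,
      temperature = attr(series, "temperature"),
      n_points_used = sum(keep),
      excluded = excluded
    ),
    class = "isotherm_fit"
  )
}

## Direct (nonlinear) fit of A = A0 + (A_inf - A0) * K L / (1 + K L).
## Used as a cross-check on the linearised estimate and as the noise-floor
## estimator; failure to converge is tolerated (returns NULL fields).
direct_hyperbola_fit <- function(L, A, A0) {
  dA_last <- A[length(A)] - A0
  start <- list(K = 1 / stats::median(L), dA = dA_last * 1.5)
  out <- tryCatch({
    fit <- minpack.lm::nlsLM(
      A ~ A0 + dA * K * L / (1 + K * L),
      start = start,
      data = data.frame(L = L, A = A),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    k <- unname(coef(fit)["K"])
    list(K_b = if (k > 0) k else NULL,
         resid_sd = if (length(A) > 3) sd(resid(fit)) else 0)
  }, error = function(e) list(K_b = NULL, resid_sd = NULL))
  out
}

#' Fractional-saturation (binding isotherm) curve from a titration
#'
#' Converts raw signals into the binding ratio
#' \eqn{\nu = \alpha g} where \eqn{\alpha = (A - A_0)/(A_\infty - A_0)}
#' (clipped to `[0, 1]`), giving the isotherm the cooperativity analyses
#' consume.
#'
#' @param series A [titration_series()].
#' @param endpoints An [endpoint_pair()].
#' @param g Binding sites per protein (default 1).
#' @return A tibble with columns `ligand_total`, `signal`, `alpha`, `nu`
#'   and `bound` (bound ligand, M).
#' @export
saturation_curve <- function(series, endpoints, g = 1) {
  stopifnot(inherits(series, "titration_series"),
            inherits(endpoints, "endpoint_pair"))
  alpha <- (series$signal - endpoints$A0) / (endpoints$A_inf - endpoints$A0)
  alpha <- pmin(pmax(alpha, 0), 1)
  tibble(
    ligand_total = series$ligand_total,
    signal = series$signal,
    alpha = alpha,
    nu = alpha * g,
    bound = alpha * g * attr(series, "protein_total")
  )
}

#' Half-saturation ligand concentration
#'
#' The total ligand concentration at which half of the protein signal
#' change has occurred (\eqn{\alpha = 0.5}), found by monotone
#' piecewise-linear interpolation of \eqn{\alpha} against `ligand_total`.
#' If the titration does not span \eqn{\alpha = 0.5} the value is linearly
#' extrapolated from the final segment and flagged. Non-monotone
#' \eqn{\alpha} beyond a small tolerance triggers a warning and isotonic
#' smoothing before interpolation.
#'
#' @inheritParams saturation_curve
#' @return The half-saturation concentration (M) with attribute
#'   `extrapolated` (logical).
#' @export
half_saturation <- function(series, endpoints) {
  curve <- saturation_curve(series, endpoints, g = 1)
  L <- curve$ligand_total
  alpha <- curve$alpha
  if (any(diff(alpha) < -0.02)) {
    warn("Saturation is non-monotone beyond noise; interpolating on an isotonic fit.")
    alpha <- isoreg(L, alpha)$yf
  }
  extrapolated <- FALSE
  if (max(alpha) >= 0.5 && min(alpha) <= 0.5) {
    i <- which(alpha >= 0.5)[1]
    if (alpha[i] == 0.5 || i == 1) {
      L_half <- L[i]
    } else {
      frac <- (0.5 - alpha[i - 1]) / (alpha[i] - alpha[i - 1])
      L_half <- L[i - 1] + frac * (L[i] - L[i - 1])
    }
  } else {
    extrapolated <- TRUE
    n <- length(L)
    seg <- if (max(alpha) < 0.5) c(n - 1, n) else c(1, 2)
    slope <- (alpha[seg[2]] - alpha[seg[1]]) / (L[seg[2]] - L[seg[1]])
    L_half <- if (slope > 0) {
      L[seg[2]] + (0.5 - alpha[seg[2]]) / slope
    } else {
      NA_real_
    }
  }
  structure(L_half, extrapolated = extrapolated)
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<isotherm_fit> K_b = %.4g M^-1 (double-reciprocal; direct fit %s)\n",
           "  A0 = %.4g, A_inf = %.4g AU; L_1/2 = %.4g M%s; R^2 = %.5f; T = %.1f K\n"),
    x$K_b,
    if (is.null(x$K_b_direct)) "unavailable" else sprintf("%.4g", x$K_b_direct),
    x$endpoints$A0, x$endpoints$A_inf, x$L_half,
    if (x$L_half_extrapolated) " (extrapolated)" else "",
    x$fit$r_squared, x$temperature
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.isotherm_fit <- function(x, ...) {
  tibble(
    term = c("K_b", "K_b_direct", "A0", "A_inf", "L_half"),
    estimate = c(x$K_b, x$K_b_direct %||% NA_real_, x$endpoints$A0,
                 x$endpoints$A_inf, x$L_half),
    unit = c("M^-1", "M^-1", "AU", "AU", "M")
  )
}

#' @exportS3Method generics::glance
glance.isotherm_fit <- function(x, ...) {
  tibble(
    K_b = x$K_b,
    r.squared = x$fit$r_squared,
    nobs = x$n_points_used,
    temperature_K = x$temperature,
    L_half_extrapolated = x$L_half_extrapolated
  )
}
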