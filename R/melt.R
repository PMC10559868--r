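#' Fit a two-state thermal unfolding transition
#'
#' Extracts the melting midpoint \eqn{T_m} (the temperature at which half
#' the protein is unfolded) from an absorbance-versus-temperature trace by
#' nonlinear least squares of the two-state logistic
#' \deqn{A(T) = A_{pre} + \frac{A_{post} - A_{pre}}
#'   {1 + \exp\left((T_m - T)/w\right)}}
#' with flat pre- and post-transition baselines. A model-free midpoint
#' (where the smoothed signal crosses the baseline midpoint) is computed
#' alongside as a cross-check. A trace with no detectable transition (a
#' straight line fits as well as the sigmoid by AIC) raises an error.
#'
#' @param trace A [melt_trace()].
#' @return An object of class `melt_fit`: list with `T_m` (K), `T_m_C`
#'   (Celsius), `width` (K), `baselines` (pre, post), `T_m_modelfree` (K),
#'   `fit_quality` (R^2 of the sigmoid fit) and `label`.
#' @examples
#' tr <- gen_melt(seed = 1, T_m_C = 47, sigma = 0)
#' fit_two_state_melt(tr)
#' @export
fit_two_state_melt <- function(trace) {
  stopifnot(inherits(trace, "melt_trace"))
  T_K <- trace$temperature_K
  A <- trace$signal

  n_edge <- max(2L, floor(length(A) / 8))
  A_pre0 <- mean(head(A, n_edge))
  A_post0 <- mean(tail(A, n_edge))
  mid0 <- (A_pre0 + A_post0) / 2
  Tm0 <- T_K[which.min(abs(A - mid0))]

  sig <- tryCatch(
    minpack.lm::nlsLM(
      A ~ A_pre + (A_post - A_pre) / (1 + exp((Tm - T_K) / w)),
      start = list(A_pre = A_pre0, A_post = A_post0, Tm = Tm0, w = 2),
      data = data.frame(T_K = T_K, A = A),
      lower = c(-Inf, -Inf, min(T_K), 1e-3),
      upper = c(Inf, Inf, max(T_K), diff(range(T_K))),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  line_fit <- lm(A ~ T_K)
  if (is.null(sig) || AIC(sig) >= AIC(line_fit)) {
    abort("No transition in range: a sloped baseline describes the trace as well as a sigmoid.",
          class = "bindspectra_error_no_transition")
  }
  est <- coef(sig)
  ss_res <- sum(resid(sig)^2)
  ss_tot <- sum((A - mean(A))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot

  mf <- modelfree_midpoint(T_K, A, est[["A_pre"]], est[["A_post"]])

  structure(
    list(
      T_m = est[["Tm"]],
      T_m_C = est[["Tm"]] - 273.15,
      width = est[["w"]],
      baselines = c(pre = unname(est[["A_pre"]]),
                    post = unname(est[["A_post"]])),
      T_m_modelfree = mf,
      fit_quality = r2,
      label = attr(trace, "label") %||% ""
    ),
    class = "melt_fit"
  )
}

## Temperature at which the lightly smoothed trace crosses the midpoint of
## the fitted baselines; linear interpolation between the bracketing points.
modelfree_midpoint <- function(T_K, A, A_pre, A_post) {
  k <- min(5L, length(A))
  if (k %% 2 == 0) k <- k - 1
  sm <- stats::filter(A, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- A[is.na(sm)]
  mid <- (A_pre + A_post) / 2
  s <- sign(sm - mid)
  cross <- which(s[-1] != s[-length(s)] & s[-1] != 0)
  if (length(cross) == 0) return(NA_real_)
  i <- cross[1]
  frac <- (mid - sm[i]) / (sm[i + 1] - sm[i])
  T_K[i] + frac * (T_K[i + 1] - T_K[i])
}

#' Melting-temperature shift on ligand binding
#'
#' \eqn{\Delta T_m = T_m(\mathrm{bound}) - T_m(\mathrm{free})}; a positive
#' shift means ligand binding thermally stabilises the protein.
#'
#' @param free,bound [melt_trace()] objects for the free and ligand-bound
#'   protein.
#' @return A tibble with one row: `T_m_free_K`, `T_m_bound_K`,
#'   `delta_T_m_K` and `verdict` (`"stabilizing"`, `"destabilizing"` or
#'   `"neutral"`).
#' @export
tm_shift <- function(free, bound) {
  f <- fit_two_state_melt(free)
  b <- fit_two_state_melt(bound)
  d <- b$T_m - f$T_m
  tibble(
    T_m_free_K = f$T_m,
    T_m_bound_K = b$T_m,
    delta_T_m_K = d,
    verdict = if (d > 0) "stabilizing" else if (d < 0) "destabilizing" else "neutral"
  )
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf(
    "<melt_fit>%s T_m = %.2f K (%.2f C), width = %.2f K, baselines %.3g -> %.3g (R^2 = %.5f)\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    x$T_m, x$T_m_C, x$width, x$baselines[["pre"]], x$baselines[["post"]],
    x$fit_quality
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.melt_fit <- function(x, ...) {
  tibble(
    term = c("T_m", "width", "A_pre", "A_post", "T_m_modelfree"),
    estimate = c(x$T_m, x$width, x$baselines[["pre"]],
                 x$baselines[["post"]], x$T_m_modelfree),
    unit = c("K", "K", "AU", "AU", "K")
  )
}

#' @exportS3Method generics::glance
glance.melt_fit <- function(x, ...) {
  tibble(T_m_K = x$T_m, T_m_C = x$T_m_C, width_K = x$width,
         r.squared = x$fit_quality, label = x$label)
}
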