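#' Integrated first-order rate-law fit
#'
#' Linearises the first-order approach to equilibrium,
#' \deqn{\ln(A_\infty - A) = -a k t + \ln(A_\infty - A_0),}
#' by regressing \eqn{\ln|A_\infty - A|} on time. The rate constant is
#' `-slope / a` (the stoichiometric factor `a` defaults to 1, since the
#' monitored concentrations are not resolved). Points with
#' \eqn{|A_\infty - A| = 0} (signal at or past the endpoint) are excluded
#' with a warning. The fitted intercept is cross-checked against
#' \eqn{\ln|A_\infty - A_0|} and the discrepancy reported.
#'
#' @param trace A [kinetic_trace()].
#' @param a Stoichiometric factor (default 1).
#' @return A list of class `rate_fit`: `order` (1), `k` (s^-1), `fit`
#'   (a [fit_line()] on the transformed axes), `intercept_expected`,
#'   `n_points_used`.
#' @export
first_order_fit <- function(trace, a = 1) {
  rate_law_fit(trace, order = 1L, a = a)
}

#' Integrated second-order rate-law fit
#'
#' Linearises the second-order approach to equilibrium,
#' \deqn{\frac{1}{A_\infty - A} = a k t + \frac{1}{A_\infty - A_0},}
#' by regressing \eqn{1/(A_\infty - A)} on time; the slope is the
#' composite \eqn{a k} (AU^-1 s^-1), reported as-is because separating
#' `a` requires concentration information the trace does not carry.
#'
#' @inheritParams first_order_fit
#' @return A list of class `rate_fit`: `order` (2), `k` (the composite
#'   a*k, AU^-1 s^-1), `fit`, `intercept_expected`, `n_points_used`.
#' @export
second_order_fit <- function(trace, a = 1) {
  rate_law_fit(trace, order = 2L, a = a)
}

rate_law_fit <- function(trace, order, a = 1) {
  stopifnot(inherits(trace, "kinetic_trace"))
  A_inf <- attr(trace, "A_inf")
  A0 <- attr(trace, "A0")
  gap <- A_inf - trace$signal
  keep <- abs(gap) > 0 & sign(gap) == sign(A_inf - A0)
  if (any(!keep)) {
    warn(sprintf(
      "%d point(s) at or beyond A_inf excluded from the order-%d transform.",
      sum(!keep), order
    ))
  }
  if (sum(keep) < 3) {
    abort("Fewer than 3 usable points before the endpoint.",
          class = "bindspectra_error")
  }
  t <- trace$time[keep]
  if (order == 1L) {
    y <- log(abs(gap[keep]))
    expected_intercept <- log(abs(A_inf - A0))
  } else {
    y <- 1 / abs(gap[keep])
    expected_intercept <- 1 / abs(A_inf - A0)
  }
  fit <- fit_line(t, y)
  decline <- abs(fit$slope) * diff(range(t))
  if (order == 1L &&
      (fit$slope >= 0 || decline < 1e-8 * (1 + abs(mean(y))))) {
    abort("Signal does not approach A_inf (no first-order decay detectable).",
          class = "bindspectra_error")
  }
  k <- if (order == 1L) -fit$slope / a else fit$slope / a
  structure(
    list(
      order = order,
      k = k,
      fit = fit,
      intercept_expected = expected_intercept,
      intercept_discrepancy = fit$intercept - expected_intercept,
      n_points_used = sum(keep)
    ),
    class = "rate_fit"
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  unit <- if (x$order == 1L) "s^-1" else "AU^-1 s^-1"
  cat(sprintf("<rate_fit> order %d: k = %.4g %s (R^2 = %.6f, n = %d)\n",
              x$order, x$k, unit, x$fit$r_squared, x$n_points_used))
  invisible(x)
}

#' Select the reaction order by linearisation quality
#'
#' Fits both integrated rate laws and chooses the order whose linearised
#' plot is straighter (larger \eqn{R^2}), the standard graphical
#' discrimination. The margin \eqn{\Delta R^2} is reported; margins below
#' `tie_margin` are flagged indeterminate.
#'
#' @inheritParams first_order_fit
#' @param tie_margin \eqn{\Delta R^2} below which the comparison is called
#'   indeterminate (default 0.001).
#' @return An object of class `order_selection`: list with `first` and
#'   `second` ([first_order_fit()]/[second_order_fit()] results), `chosen`
#'   (`"first"` or `"second"`), `margin` and `indeterminate` (logical).
#' @examples
#' tr <- gen_kinetic(seed = 1, order = 2, sigma = 0)
#' select_order(tr)
#' @export
select_order <- function(trace, a = 1, tie_margin = 0.001) {
  f1 <- first_order_fit(trace, a = a)
  f2 <- second_order_fit(trace, a = a)
  r2 <- c(first = f1$fit$r_squared, second = f2$fit$r_squared)
  chosen <- names(which.max(r2))
  margin <- abs(diff(r2))
  structure(
    list(
      first = f1,
      second = f2,
      chosen = chosen,
      margin = unname(margin),
      indeterminate = margin < tie_margin
    ),
    class = "order_selection"
  )
}

#' @export
print.order_selection <- function(x, ...) {
  cat(sprintf(
    "<order_selection> chosen: %s order (R^2 %.6f vs %.6f, margin %.2e%s)\n",
    x$chosen, x$first$fit$r_squared, x$second$fit$r_squared, x$margin,
    if (x$indeterminate) "; indeterminate" else ""
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.order_selection <- function(x, ...) {
  tibble(
    order = c("first", "second"),
    k = c(x$first$k, x$second$k),
    unit = c("s^-1", "AU^-1 s^-1"),
    r.squared = c(x$first$fit$r_squared, x$second$fit$r_squared),
    chosen = c(x$chosen == "first", x$chosen == "second")
  )
}

#' @exportS3Method generics::glance
glance.order_selection <- function(x, ...) {
  tibble(chosen = x$chosen, margin = x$margin,
         indeterminate = x$indeterminate)
}
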