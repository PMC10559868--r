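#' Ordinary least-squares line fit
#'
#' Every linearised analysis in the package (double-reciprocal, Hill,
#' Stern-Volmer, double-log, integrated rate laws, binding-capacity
#' diagnostic) reduces to a straight-line regression reported as slope,
#' intercept and \eqn{R^2}. `fit_line()` is that shared primitive.
#'
#' @param x,y Numeric vectors of equal length (at least 2 points). `x` must
#'   not be constant.
#'
#' @return An object of class `line_fit`: a list with elements `slope`,
#'   `intercept`, `r_squared` and `n_points`. `r_squared` is
#'   \eqn{1 - SS_{res}/SS_{tot}}, defined as 1 for an exact fit to constant
#'   `y` (both sums of squares zero).
#'
#' @examples
#' fit_line(c(0, 1, 2), c(1, 3, 5))
#' @export
fit_line <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.", class = "bindspectra_error")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 2) {
    abort("At least 2 finite (x, y) points are required.",
          class = "bindspectra_error")
  }
  if (diff(range(x)) == 0) {
    abort("`x` values are all equal: slope is not identifiable.",
          class = "bindspectra_error_degenerate_x")
  }
  fit <- lm(y ~ x)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res <= .Machine$double.eps * length(y)) 1 else 0
  } else {
    max(0, min(1, 1 - ss_res / ss_tot))
  }
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = r2,
      n_points = length(x)
    ),
    class = "line_fit"
  )
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf(
    "<line_fit> slope = %.6g, intercept = %.6g, R^2 = %.6f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n_points
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.line_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @exportS3Method generics::glance
glance.line_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n_points)
}
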