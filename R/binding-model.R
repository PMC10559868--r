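#' Binding parameters for one set of identical sites
#'
#' Bundles the parameters of the single-set Hill binding model used
#' throughout the package: the association constant `K_b` (M^-1), the number
#' of sites per protein `g`, the Hill coefficient `n_H` and the Hill
#' constant `K_H` (M^-n_H). For a non-cooperative single site
#' (`n_H = 1`, `g = 1`) the Hill constant and the association constant
#' coincide.
#'
#' @param K_b Association constant, M^-1. Must be positive.
#' @param g Binding sites per protein molecule. Must be positive.
#' @param n_H Hill coefficient. Must be positive.
#' @param K_H Hill constant, M^-n_H. Defaults to `K_b^n_H`, which reduces to
#'   `K_b` in the non-cooperative case.
#'
#' @return A list of class `binding_parameters`.
#' @examples
#' binding_parameters(K_b = 6778, g = 1)
#' @export
binding_parameters <- function(K_b, g = 1, n_H = 1, K_H = K_b^n_H) {
  stopifnot(is.numeric(K_b), is.numeric(g), is.numeric(n_H), is.numeric(K_H))
  if (K_b <= 0 || g <= 0 || n_H <= 0 || K_H <= 0) {
    abort("All binding parameters (K_b, g, n_H, K_H) must be positive.",
          class = "bindspectra_error")
  }
  structure(
    list(K_b = K_b, g = g, n_H = n_H, K_H = K_H),
    class = "binding_parameters"
  )
}

#' @export
print.binding_parameters <- function(x, ...) {
  cat(sprintf(
    "<binding_parameters> K_b = %.4g M^-1, g = %.3g, n_H = %.3g, K_H = %.4g\n",
    x$K_b, x$g, x$n_H, x$K_H
  ))
  invisible(x)
}

#' Forward single-set Hill binding model
#'
#' Moles of ligand bound per mole of protein at a given free-ligand
#' concentration, \deqn{\nu = g K_H [L]_f^{n_H} / (1 + K_H [L]_f^{n_H}),}
#' the saturation form of the Hill relation
#' \eqn{\ln(\nu/(g-\nu)) = \ln K_H + n_H \ln [L]_f}.
#'
#' @param L_free Free ligand concentration, M (scalar or vector, >= 0).
#' @param params A [binding_parameters()] object.
#'
#' @return The binding ratio \eqn{\nu}, in `[0, g)`, monotone non-decreasing
#'   in `L_free`.
#' @examples
#' p <- binding_parameters(K_b = 1e4, g = 2)
#' nu_forward(1e-4, p)
#' @export
nu_forward <- function(L_free, params) {
  stopifnot(inherits(params, "binding_parameters"))
  if (any(L_free < 0)) {
    abort("`L_free` must be non-negative.", class = "bindspectra_error")
  }
  x <- params$K_H * L_free^params$n_H
  params$g * x / (1 + x)
}

#' Solve the ligand mass balance for free ligand
#'
#' Titrations are prepared by total ligand concentration, while the binding
#' model is written in free ligand. The two are linked by conservation,
#' \eqn{[L]_t = [L]_f + \nu [P]_t}, which this function solves for
#' \eqn{[L]_f} by bracketed root finding on `[0, L_total]` (the residual is
#' strictly monotone on that interval, so the bracket is guaranteed).
#'
#' @param L_total Total ligand concentration, M (scalar or vector, >= 0).
#' @param P_total Total protein concentration, M (> 0).
#' @param params A [binding_parameters()] object.
#' @param tol Relative convergence tolerance on the mass-balance residual.
#'
#' @return A tibble with columns `L_total`, `L_free` and `nu`, one row per
#'   input concentration.
#' @examples
#' p <- binding_parameters(K_b = 1e6)
#' solve_mass_balance(1e-5, P_total = 1.5e-5, params = p)
#' @export
solve_mass_balance <- function(L_total, P_total, params, tol = 1e-12) {
  stopifnot(inherits(params, "binding_parameters"))
  if (any(L_total < 0) || P_total <= 0) {
    abort("Require L_total >= 0 and P_total > 0.", class = "bindspectra_error")
  }
  g <- params$g
  K <- params$K_H
  n <- params$n_H
  L_free <- purrr::map_dbl(L_total, function(Lt) {
    if (Lt == 0) return(0)
    residual <- function(Lf) Lf + nu_forward(Lf, params) * P_total - Lt
    root <- uniroot(residual, lower = 0, upper = Lt,
                    tol = .Machine$double.eps * Lt, maxiter = 2000)$root
    # Newton polish: the root can sit on a steep flank where interval
    # bisection alone leaves a residual above the requested tolerance.
    for (i in seq_len(8)) {
      if (abs(residual(root)) <= tol * Lt) break
      x <- K * root^n
      deriv <- 1 + P_total * g * K * n * root^(n - 1) / (1 + x)^2
      step <- residual(root) / deriv
      cand <- min(max(root - step, 0), Lt)
      if (abs(residual(cand)) < abs(residual(root))) root <- cand else break
    }
    if (abs(residual(root)) > tol * Lt) {
      abort(sprintf(
        "Mass-balance solve did not converge: residual %.3e at L_total = %.3e M.",
        residual(root), Lt
      ), class = "bindspectra_error_convergence")
    }
    root
  })
  tibble(
    L_total = as.numeric(L_total),
    L_free = L_free,
    nu = nu_forward(L_free, params)
  )
}
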