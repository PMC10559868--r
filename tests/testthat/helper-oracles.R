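# Independent oracles used to freeze expected values. Each is deliberately
# naive (closed forms evaluated step by step), so it cannot share a defect
# with the implementation path it checks.

# OLS by the raw normal equations.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# Free ligand for the 1:1 (n_H = 1, g = 1) model with depletion:
# positive root of K L^2 + (1 + K (P - Lt)) L - Lt = 0.
quadratic_free_ligand <- function(K, P, Lt) {
  b <- 1 + K * (P - Lt)
  (-b + sqrt(b^2 + 4 * K * Lt)) / (2 * K)
}

# Numeric inversion of the Hill relation: the L_free at which nu reaches a
# target value, by bisection on the monotone forward curve.
invert_hill_oracle <- function(nu_target, g, K_H, n_H,
                               upper = 1, iter = 200) {
  f <- function(L) g * K_H * L^n_H / (1 + K_H * L^n_H) - nu_target
  lo <- 0; hi <- upper
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
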