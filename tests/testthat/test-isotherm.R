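test_that("exact points on the double-reciprocal line invert algebraically", {
  # 1/(A - A0) = intercept + slope / [L] with intercept 2 AU^-1,
  # slope 1e-3 AU^-1 M: K_b = intercept/slope = 2000, A_inf = A0 + 0.5
  A0 <- 0.2
  L <- c(1e-3, 2e-3, 4e-3)
  A <- A0 + 1 / (2 + 1e-3 / L)
  s <- titration_series(L, A, protein_total = 1e-9, temperature = 300)
  fit <- double_reciprocal_fit(s, A0 = A0, noise_floor = 0)
  expect_equal(fit$K_b, 2000, tolerance = 1e-9)
  expect_equal(fit$endpoints$A_inf, A0 + 0.5, tolerance = 1e-9)
})

test_that("noiseless forward simulations are inverted in the low-depletion regime", {
  p <- binding_parameters(K_b = 5000)
  s <- gen_uv_titration(seed = 1, params = p, sigma = 0,
                        protein_total = 1e-12)
  fit <- suppressWarnings(double_reciprocal_fit(s))
  expect_rel(fit$K_b, 5000, 1e-3)
  expect_gt(fit$fit$r_squared, 0.9999)
  # the direct hyperbola cross-check agrees on noiseless data
  expect_rel(fit$K_b_direct, 5000, 1e-3)

  # automated regime check: whenever depletion stays below 1 percent the
  # generating constant is recovered to 0.1 percent
  set.seed(21)
  for (i in 1:5) {
    K <- 10^runif(1, 3, 5)
    P <- 1e-9
    grid <- 10^seq(log10(0.1 / K), log10(10 / K), length.out = 10)
    s <- gen_uv_titration(seed = i, params = binding_parameters(K),
                          protein_total = P, grid = grid, sigma = 0)
    truth <- attr(s, "truth")
    depletion <- max((s$ligand_total[-1] - truth$L_free[-1]) /
                       s$ligand_total[-1])
    expect_lt(depletion, 0.01)
    fit <- suppressWarnings(double_reciprocal_fit(s))
    expect_rel(fit$K_b, K, 1e-3)
  }
})

test_that("K_b near 6778 M^-1 is recovered under 0.5% noise (median of 50 seeds)", {
  grid <- 10^seq(log10(2e-5), log10(1.5e-3), length.out = 12)
  ks <- vapply(1:50, function(sd) {
    s <- gen_uv_titration(seed = sd, protein_total = 0.15e-6, grid = grid)
    suppressWarnings(double_reciprocal_fit(s)$K_b)
  }, numeric(1))
  expect_rel(median(ks), 6778, 0.05)
})

test_that("saturation_curve maps endpoints to nu = 0 and nu = g", {
  ep <- endpoint_pair(0.6, 0.2)
  g <- 3.8
  s <- titration_series(c(1e-6, 2e-6, 3e-6), c(0.6, 0.4, 0.2),
                        protein_total = 15e-6, temperature = 300)
  curve <- saturation_curve(s, ep, g = g)
  expect_equal(curve$nu, c(0, g / 2, g))
  expect_equal(curve$nu[2], 1.9) # alpha = 0.5 at g = 3.8
  expect_equal(curve$bound, curve$nu * 15e-6)
})

test_that("half_saturation interpolates, extrapolates and rescales", {
  ep <- endpoint_pair(0, 1)
  s <- titration_series(c(0, 10e-6, 20e-6), c(0, 0.5, 1),
                        protein_total = 1e-9, temperature = 300)
  expect_equal(as.numeric(half_saturation(s, ep)), 10e-6)

  s2 <- titration_series(c(0, 10e-6, 20e-6), c(0, 0.4, 0.8),
                         protein_total = 1e-9, temperature = 300)
  h2 <- half_saturation(s2, endpoint_pair(0, 1))
  expect_equal(as.numeric(h2), 12.5e-6)
  expect_false(attr(h2, "extrapolated"))

  # half-saturation at 1/K_H for the 1:1 model, negligible depletion
  p <- binding_parameters(K_b = 1e6)
  grid <- 10^seq(-7.5, -4.5, length.out = 15)
  s3 <- gen_uv_titration(seed = 1, params = p, protein_total = 1e-12,
                         grid = grid, sigma = 0,
                         endpoints = endpoint_pair(0, 1))
  h3 <- half_saturation(s3, endpoint_pair(0, 1))
  expect_rel(as.numeric(h3), 1e-6, 0.01)

  # invariant under uniform rescaling of the signal axis
  s4 <- titration_series(s3$ligand_total, s3$signal * 7.3,
                         protein_total = 1e-12, temperature = 300)
  h4 <- half_saturation(s4, endpoint_pair(0, 7.3))
  expect_equal(as.numeric(h4), as.numeric(h3))

  # not spanned: flagged extrapolated
  s5 <- titration_series(c(1e-6, 2e-6, 3e-6), c(0.10, 0.2, 0.3),
                         protein_total = 1e-9, temperature = 300)
  h5 <- half_saturation(s5, endpoint_pair(0, 1))
  expect_true(attr(h5, "extrapolated"))
})

test_that("non-saturating data raise an informative error", {
  # signal accelerating away from the baseline (no asymptote) gives a
  # reciprocal plot whose intercept/slope ratio is negative
  L <- c(1e-6, 2e-6, 3e-6, 4e-6)
  A <- 0.2 - 5e9 * L^2
  s <- titration_series(L, A, protein_total = 1e-9, temperature = 300)
  expect_error(double_reciprocal_fit(s, A0 = 0.2, noise_floor = 0),
               class = "bindspectra_error_nonsaturating")
})
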