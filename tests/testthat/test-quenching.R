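test_that("stern_volmer_fit inverts exact linear quenching", {
  Q <- seq(0, 2e-4, length.out = 10)
  s <- quench_series(Q, 1000 / (1 + 1e4 * Q), F0 = 1000)
  fit <- stern_volmer_fit(s)
  expect_equal(fit$K_sv, 1e4, tolerance = 1e-9)
  expect_equal(fit$fit$intercept, 1, tolerance = 1e-9)
  expect_false(fit$curvature_warning)

  # unquenched series: zero constant
  s0 <- quench_series(Q, rep(1000, 10), F0 = 1000)
  expect_equal(stern_volmer_fit(s0)$K_sv, 0)
})

test_that("combined static-dynamic curvature is detected and confined", {
  s <- gen_quench_titration(seed = 1, K_sv = 1e4, K_a = 8e3, sigma = 0)
  expect_warning(fit <- stern_volmer_fit(s), "curvature")
  expect_lt(fit$n_points_used, nrow(s))
  # restricting to the low-concentration window pulls the slope from the
  # whole-range value toward the product model's initial slope K_sv + K_a
  full <- fit_line(s$Q, attr(s, "F0") / s$F_signal)
  expect_lt(fit$K_sv, full$slope)
  expect_gt(fit$K_sv, 1.8e4 * 0.9)
  expect_lt(fit$K_sv, full$slope * 0.9)
})

test_that("rising fluorescence is rejected", {
  Q <- seq(0, 1e-4, length.out = 6)
  s <- suppressWarnings(quench_series(Q, 1000 * (1 + 5e3 * Q), F0 = 1000))
  expect_error(stern_volmer_fit(s), class = "bindspectra_error")
})

test_that("quenching mechanism uses the diffusion limit strictly", {
  m1 <- quenching_mechanism(1e4, 1e-8)
  expect_equal(m1$k_q, 1e12)
  expect_equal(m1$mechanism, "static")
  expect_equal(quenching_mechanism(1e2, 1e-8)$mechanism, "dynamic")
  # exactly at 2e10: strict inequality, still dynamic
  expect_equal(quenching_mechanism(2e2, 1e-8)$mechanism, "dynamic")
})

test_that("double_log_fit inverts the binding model exactly", {
  s <- gen_quench_titration(seed = 1, model = "double_log",
                            K_b_dl = 5e6, n_dl = 1.3, sigma = 0)
  fit <- double_log_fit(s)
  expect_rel(fit$K_b, 5e6, 1e-6)
  expect_equal(fit$n_sites, 1.3, tolerance = 1e-9)

  # n = 1 data: unit slope, intercept log10(K_b)
  s1 <- gen_quench_titration(seed = 1, model = "double_log",
                             K_b_dl = 2e4, n_dl = 1, sigma = 0)
  f1 <- double_log_fit(s1)
  expect_equal(f1$n_sites, 1, tolerance = 1e-9)
  expect_equal(f1$fit$intercept, log10(2e4), tolerance = 1e-9)
})

test_that("site number is recovered within 0.1 over a single decade of Q", {
  grid <- c(0, 10^seq(-5.5, -4.5, length.out = 10))
  ns <- vapply(1:50, function(sd) {
    s <- suppressWarnings(
      gen_quench_titration(seed = sd, model = "double_log", grid = grid,
                           K_b_dl = 5e6, n_dl = 1.3, sigma = 0.01)
    )
    suppressWarnings(double_log_fit(s)$n_sites)
  }, numeric(1))
  expect_lt(abs(median(ns) - 1.3), 0.1)
})

test_that("mechanism verdict is invariant to uniform intensity rescaling", {
  s <- gen_quench_titration(seed = 2, K_sv = 5e3, sigma = 0.005)
  base <- analyze_quenching(s)
  scaled <- quench_series(s$Q, s$F_signal * 3.7,
                          F0 = attr(s, "F0") * 3.7,
                          tau0 = attr(s, "tau0"))
  resc <- analyze_quenching(scaled)
  expect_equal(resc$mechanism, base$mechanism)
  expect_equal(resc$K_sv, base$K_sv, tolerance = 1e-9)
})

test_that("analyze_quenching chains all three analyses", {
  s <- gen_quench_titration(seed = 3, model = "double_log", sigma = 0)
  res <- suppressWarnings(analyze_quenching(s))
  expect_equal(res$mechanism, "static")
  expect_rel(res$K_b_doublelog, 5e6, 1e-3)
  expect_equal(res$n_sites, 1.3, tolerance = 1e-3)
  expect_equal(res$k_q, res$K_sv / attr(s, "tau0"))
  td <- tidy(res)
  expect_equal(td$term, c("K_sv", "k_q", "K_b", "n"))
})
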