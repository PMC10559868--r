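test_that("binding_capacity vanishes at the ends and follows the formula", {
  p <- binding_parameters(K_b = 100, g = 4, n_H = 2)
  expect_equal(binding_capacity(0, p, 300), 0)
  expect_equal(binding_capacity(4, p, 300), 0)
  expect_equal(binding_capacity(2, p, 300),
               2 * 2 * (4 - 2) / (4 * 8.314 * 300))
  # maximum at nu = g/2
  nu <- seq(0, 4, by = 0.1)
  theta <- binding_capacity(nu, p, 300)
  expect_equal(nu[which.max(theta)], 2)
  expect_error(binding_capacity(4.5, p, 300), class = "bindspectra_error")
})

test_that("capacity diagnostic recovers n_H and g from exact capacity data", {
  p <- binding_parameters(K_b = 100, g = 1.9, n_H = 1.8)
  pts <- tibble::tibble(nu = seq(0.1, 1.8, by = 0.1), L_free = NA_real_)
  diag <- capacity_diagnostic(pts, p, T = 300)
  expect_equal(diag$intercept, 1.8, tolerance = 1e-9)
  expect_equal(diag$slope, -1.8 / 1.9, tolerance = 1e-9)
  expect_equal(diag$n_H, 1.8, tolerance = 1e-9)
  expect_equal(diag$g, 1.9, tolerance = 1e-9)
  expect_gt(diag$r_squared, 1 - 1e-12)
  expect_true(diag$single_set)

  simple <- capacity_diagnostic(
    tibble::tibble(nu = c(0.2, 0.4, 0.6, 0.8)),
    binding_parameters(K_b = 10, g = 1, n_H = 1), T = 310
  )
  expect_equal(simple$intercept, 1, tolerance = 1e-9)
  expect_equal(simple$slope, -1, tolerance = 1e-9)
})

test_that("hill_fit inverts the forward model and classifies cooperativity", {
  # exact data from n_H = 1.8, K_H = 19.1 (concentration units where the
  # half-saturation point sits near 0.2)
  p <- binding_parameters(K_b = 19.1^(1 / 1.8), g = 2, n_H = 1.8,
                          K_H = 19.1)
  L <- 10^seq(-2, 0.5, length.out = 12)
  pts <- tibble::tibble(L_free = L, nu = nu_forward(L, p))
  h <- hill_fit(pts, g = 2)
  expect_equal(h$n_H, 1.8, tolerance = 1e-9)
  expect_equal(h$K_H, 19.1, tolerance = 1e-9)
  expect_equal(h$cooperativity, "positive")

  # non-cooperative data
  p1 <- binding_parameters(K_b = 1e5)
  L <- 10^seq(-6.5, -3.5, length.out = 10)
  pts1 <- tibble::tibble(L_free = L, nu = nu_forward(L, p1))
  h1 <- hill_fit(pts1, g = 1)
  expect_equal(h1$n_H, 1, tolerance = 1e-9)
  expect_equal(h1$cooperativity, "non_cooperative")

  expect_error(hill_fit(tibble::tibble(nu = c(0, 1), L_free = c(0, 1)),
                        g = 1),
               class = "bindspectra_error")
})

test_that("hill_fit composed with nu_forward is the identity on (K_H, n_H)", {
  set.seed(9)
  for (i in 1:20) {
    g <- runif(1, 0.5, 4)
    n_H <- runif(1, 0.5, 2.5)
    K_H <- 10^runif(1, 2, 8)
    p <- binding_parameters(K_b = K_H^(1 / n_H), g = g, n_H = n_H,
                            K_H = K_H)
    L_half <- (1 / K_H)^(1 / n_H)
    L <- L_half * 10^seq(-1, 1, length.out = 11)
    pts <- tibble::tibble(L_free = L, nu = nu_forward(L, p))
    h <- hill_fit(pts, g = g)
    expect_equal(h$n_H, n_H, tolerance = 1e-6)
    expect_equal(h$K_H, K_H, tolerance = 1e-6)
  }
})

test_that("scatchard classifies shape and matches the Hill verdict", {
  make_pts <- function(n_H, g = 1, K_H = 1e5) {
    p <- binding_parameters(K_b = K_H^(1 / n_H), g = g, n_H = n_H,
                            K_H = K_H)
    L_half <- (1 / K_H)^(1 / n_H)
    L <- L_half * 10^seq(-1.2, 1.2, length.out = 15)
    tibble::tibble(L_free = L, nu = nu_forward(L, p))
  }

  # single-site data: straight line, slope -K, intercept gK
  pts1 <- make_pts(1, g = 2, K_H = 1e5)
  sc1 <- scatchard(pts1)
  expect_equal(sc1$classification, "non_cooperative")
  line <- fit_line(sc1$curve$nu, sc1$curve$nu_over_L)
  expect_equal(line$slope, -1e5, tolerance = 1e-6)
  expect_equal(line$intercept, 2 * 1e5, tolerance = 1e-6)

  expect_equal(scatchard(make_pts(1.8))$classification, "positive")
  expect_equal(scatchard(make_pts(0.5))$classification, "negative")

  # agreement with sign(n_H - 1) across the forward-model family
  for (n_H in c(0.5, 1, 1.5, 2, 3)) {
    verdict <- scatchard(make_pts(n_H))$classification
    expected <- if (n_H > 1) "positive" else if (n_H < 1) "negative"
    else "non_cooperative"
    expect_equal(verdict, expected)
  }
})

test_that("gibbs_per_site slope is analytically RT(1 - n_H)", {
  p <- binding_parameters(K_b = 19.1^(1 / 1.8), g = 2, n_H = 1.8,
                          K_H = 19.1)
  L <- 10^seq(-2, 0, length.out = 8)
  pts <- tibble::tibble(L_free = L, nu = nu_forward(L, p))
  h <- hill_fit(pts, g = 2)
  gp <- gibbs_per_site(pts, h, T = 300)
  expect_equal(unique(gp$slope_kJ_mol), 8.314 * 300 * (1 - 1.8) / 1000)
  # the tabulated points lie exactly on that line
  line <- fit_line(gp$ln_L_free, gp$delta_G_kJ_mol)
  expect_equal(line$slope, 8.314 * 300 * (-0.8) / 1000, tolerance = 1e-9)
  expect_equal(attr(gp, "cooperativity"), "positive")

  # n_H = 1: constant delta_G = -RT ln K_H
  p1 <- binding_parameters(K_b = 1e4)
  pts1 <- tibble::tibble(L_free = 10^seq(-5, -3, length.out = 6),
                         nu = nu_forward(10^seq(-5, -3, length.out = 6), p1))
  h1 <- hill_fit(pts1, g = 1, occupancy_window = c(0, 1))
  gp1 <- gibbs_per_site(pts1, h1, T = 300)
  expect_equal(unique(gp1$slope_kJ_mol), 0, tolerance = 1e-9)
  expect_equal(gp1$delta_G_kJ_mol,
               rep(-8.314 * 300 * log(1e4) / 1000, 6), tolerance = 1e-6)

  # n_H < 1 gives a positive slope, corroborating negative cooperativity
  p5 <- binding_parameters(K_b = 1e4, n_H = 0.5, K_H = 100)
  L5 <- 10^seq(-6, -2, length.out = 8)
  pts5 <- tibble::tibble(L_free = L5, nu = nu_forward(L5, p5))
  h5 <- hill_fit(pts5, g = 1)
  gp5 <- gibbs_per_site(pts5, h5, T = 300)
  expect_gt(unique(gp5$slope_kJ_mol), 0)
  expect_equal(attr(gp5, "cooperativity"), "negative")
})
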