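make_bundle <- function(dir) {
  grid <- 10^seq(log10(2e-5), log10(1.5e-3), length.out = 12)
  t300 <- gen_uv_titration(seed = 41, protein_total = 0.15e-6,
                           grid = grid, sigma = 0.002)
  t310 <- gen_uv_titration(seed = 42,
                           params = binding_parameters(K_b = 3038),
                           protein_total = 0.15e-6, grid = grid,
                           temperature = 310, sigma = 0.002)
  write_series(t300, file.path(dir, "titration_300K.csv"))
  write_series(t310, file.path(dir, "titration_310K.csv"))
  write_series(gen_melt(seed = 43, T_m_C = 37, sigma = 0.003,
                        noise = "additive", label = "free"),
               file.path(dir, "melt_free.csv"))
  write_series(gen_melt(seed = 44, T_m_C = 47, sigma = 0.003,
                        noise = "additive", label = "bound"),
               file.path(dir, "melt_bound.csv"))
  write_series(gen_kinetic(seed = 45, order = 2, sigma = 0.005),
               file.path(dir, "kinetic.csv"))
  write_series(gen_quench_titration(seed = 46, model = "double_log",
                                    sigma = 0),
               file.path(dir, "quench.csv"))
  list(
    isotherm = list(
      list(path = file.path(dir, "titration_300K.csv"),
           protein_total = 0.15e-6, temperature = 300),
      list(path = file.path(dir, "titration_310K.csv"),
           protein_total = 0.15e-6, temperature = 310)
    ),
    cooperativity = list(series = 1, g = 1),
    melt = list(free = file.path(dir, "melt_free.csv"),
                bound = file.path(dir, "melt_bound.csv")),
    kinetics = list(path = file.path(dir, "kinetic.csv"),
                    A0 = 0.60, A_inf = 0.85),
    quench = list(path = file.path(dir, "quench.csv"))
  )
}

test_that("a melt-only config yields a melt-only report", {
  dir <- withr::local_tempdir()
  cfg <- make_bundle(dir)
  report <- run_study(list(melt = cfg$melt))
  expect_s3_class(report, "study_report")
  expect_named(report, c("melt", "provenance"))
  expect_equal(report$melt$shift$verdict, "stabilizing")
})

test_that("the full synthetic bundle is recovered within tolerances", {
  dir <- withr::local_tempdir()
  cfg <- make_bundle(dir)
  report <- suppressWarnings(run_study(cfg))

  # single noisy series each: wide single-seed tolerance (precision of the
  # estimator itself is characterised by the 50-seed median test)
  expect_rel(report$isotherm[[1]]$K_b, 6778, 0.35)
  expect_rel(report$isotherm[[2]]$K_b, 3038, 0.35)
  # two-temperature chain satisfies dG = dH - T dS at both temperatures
  th <- report$thermo
  expect_equal(th$delta_G_kJ_mol,
               th$delta_H_kJ_mol - th$temperature_K * th$delta_S_J_mol_K / 1000,
               tolerance = 1e-9)
  expect_lt(abs(report$melt$shift$delta_T_m_K - 10), 0.3)
  expect_equal(report$kinetics$chosen, "second")
  expect_equal(report$quench$mechanism, "static")
  expect_rel(report$quench$K_b_doublelog, 5e6, 0.05)
  expect_lt(abs(report$quench$n_sites - 1.3), 0.05)
  # near-ideal single-site input: Hill analysis close to non-cooperative
  expect_lt(abs(report$cooperativity$hill$n_H - 1), 0.3)
})

test_that("JSON config files and report serialisation round-trip", {
  dir <- withr::local_tempdir()
  cfg <- make_bundle(dir)
  cfg_path <- file.path(dir, "study.json")
  jsonlite::write_json(list(melt = cfg$melt, kinetics = cfg$kinetics),
                       cfg_path, auto_unbox = TRUE)
  report <- run_study(cfg_path)
  expect_equal(report$kinetics$chosen, "second")

  out <- file.path(dir, "report.json")
  write_report(report, out)
  back <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(back$melt$shift$verdict, "stabilizing")
  expect_equal(back$melt$shift$delta_T_m_K,
               report$melt$shift$delta_T_m_K, tolerance = 1e-9)
  expect_equal(back$provenance$package, "bindspectra")
})

test_that("unreadable inputs name the file", {
  expect_error(run_study(list(melt = list(free = "nope.csv",
                                          bound = "nope.csv"))))
})
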