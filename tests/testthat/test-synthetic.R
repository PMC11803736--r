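test_that("pH parameter rows are returned exactly at the tabulated pH", {
  ps <- parameter_set_for_ph(5.7)
  expect_equal(ps$D_m2_s, 4.9e-11)
  expect_equal(ps$zeta_V, 0.049)
  expect_equal(ps$zeta_surface_V, -0.030)
  # interpolation between rows and clamping outside
  mid <- parameter_set_for_ph((5.7 + 7.4) / 2)
  expect_equal(mid$zeta_V, (0.049 + 0.042) / 2)
  low <- parameter_set_for_ph(3.2)
  expect_equal(low$zeta_V, 0.049)
  expect_error(parameter_set_for_ph(12), "pH")
})

test_that("the pH 10.2 diffusion coefficient source is selectable", {
  expect_equal(parameter_set_for_ph(10.2, d_source = "range")$D_m2_s,
               5.4e-11)
  expect_equal(parameter_set_for_ph(10.2, d_source = "table")$D_m2_s,
               5.2e-11)
})

test_that("scenario defaults depend on the technique", {
  q <- experiment_scenario(5.7, "qcm")
  r <- experiment_scenario(5.7, "reflectometry")
  expect_equal(q$bulk_concentration, 5)
  expect_equal(r$bulk_concentration, 1)
  expect_equal(q$flow_rate, 1.33e-3)
  expect_equal(r$flow_rate, 1.66e-3)
  expect_error(experiment_scenario(5.7, noise_sd = -1), "noise_sd")
})

test_that("synthetic experiments are reproducible and internally consistent", {
  sc <- experiment_scenario(5.7, "qcm", duration = 300, rinse_start = 200,
                            seed = 11, sampling_dt = 5)
  e1 <- synthesize_experiment(sc, theta_max = 0.37)
  e2 <- synthesize_experiment(sc, theta_max = 0.37)
  expect_identical(e1$signal, e2$signal)
  # the noiseless signal equals the forward model of the truth
  clean <- forward_frequency_shift(e1$truth, model = e1$model,
                                   params = e1$params, medium = e1$medium,
                                   overtones = sc$overtones)
  resid <- e1$signal$neg_dfreq_over_n_hz - clean$neg_dfreq_over_n_hz
  expect_equal(sd(resid), sc$noise_sd, tolerance = 0.1)
  expect_equal(mean(resid), 0, tolerance = 3 * sc$noise_sd / sqrt(length(resid)))
})

test_that("the dimeric flag doubles the molar mass at fixed footprint", {
  sc <- experiment_scenario(5.7, "reflectometry", duration = 200,
                            rinse_start = 150, dimeric = TRUE)
  mono <- experiment_scenario(5.7, "reflectometry", duration = 200,
                              rinse_start = 150)
  ed <- synthesize_experiment(sc, theta_max = 0.37)
  em <- synthesize_experiment(mono, theta_max = 0.37)
  expect_equal(ed$molar_mass, 2 * em$molar_mass)
  expect_equal(ed$footprint_nm2, em$footprint_nm2)
})

test_that("reflectometry scenarios carry the mass signal directly", {
  sc <- experiment_scenario(7.4, "reflectometry", duration = 200,
                            rinse_start = 150, noise_sd = 0.005, seed = 3)
  ex <- synthesize_experiment(sc, theta_max = 0.40)
  expect_named(ex$signal, c("time_s", "gamma_mg_m2"))
  expect_equal(nrow(ex$signal), nrow(ex$truth))
  expect_equal(sd(ex$signal$gamma_mg_m2 - ex$truth$gamma_mg_m2), 0.005,
               tolerance = 0.15)
})

test_that("QCM and reflectometry truths share the same plateau", {
  mk <- function(technique) {
    sc <- experiment_scenario(5.7, technique, duration = 3000,
                              rinse_start = 3000,
                              bulk_concentration = 5, flow_rate = 1.33e-3)
    synthesize_experiment(sc, theta_max = 0.37)
  }
  q <- mk("qcm"); r <- mk("reflectometry")
  expect_equal(max(q$truth$gamma_mg_m2), max(r$truth$gamma_mg_m2))
})

test_that("write_experiment produces truth, signal and manifest", {
  dir <- withr::local_tempdir()
  sc <- experiment_scenario(5.7, "qcm", duration = 100, rinse_start = 80,
                            sampling_dt = 10)
  ex <- synthesize_experiment(sc, theta_max = 0.37)
  paths <- write_experiment(ex, dir, stem = "case")
  expect_true(all(file.exists(paths)))
  man <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(man$theta_max, 0.37)
  expect_equal(man$scenario$pH, 5.7)
  expect_equal(man$molar_mass, ex$molar_mass)
})
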