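#' pH-dependent electrokinetic parameters of the PARG molecule
#'
#' The measured bulk characteristics of poly-L-arginine in 100 mM NaCl:
#' diffusion coefficient (dynamic light scattering), electrophoretic
#' mobility (laser Doppler velocimetry), molecule zeta potential and the
#' silica substrate zeta potential (streaming current), at the four studied
#' pH values.
#'
#' At pH 10.2 two diffusion coefficients circulate: 5.2e-7 cm^2/s
#' (tabulated) and 5.4e-7 cm^2/s (the upper end of the measured range,
#' which also reproduces the reported hydrodynamic diameter of 9.0 nm and
#' charge number of 9.0); `d_source` selects which one derived quantities
#' use.
#'
#' @param d_source `"range"` (default; diffusion-coefficient range endpoint
#'   at pH 10.2) or `"table"` (tabulated value).
#' @return Tibble with one row per pH: `pH`, `D_m2_s`, `mobility_m2_Vs`,
#'   `zeta_V`, `zeta_surface_V`.
#' @export
ph_parameter_table <- function(d_source = c("range", "table")) {
  d_source <- match.arg(d_source)
  d10 <- if (d_source == "range") 5.4e-11 else 5.2e-11
  tibble::tibble(
    pH = c(4.0, 5.7, 7.4, 10.2),
    D_m2_s = c(4.5e-11, 4.9e-11, 4.9e-11, d10),
    mobility_m2_Vs = c(2.7e-8, 2.7e-8, 2.5e-8, 1.9e-8),
    zeta_V = c(0.049, 0.049, 0.042, 0.036),
    zeta_surface_V = c(-0.012, -0.030, -0.034, -0.043))
}

#' Electrokinetic parameter set at a given pH
#'
#' Returns the measured molecule/substrate parameters at the requested pH
#' (exact tabulated rows; linear interpolation in between) together with
#' the derived hydrodynamic diameter and electrokinetic charge.
#'
#' @param pH Solution pH, within `[3, 11]`.
#' @param medium A [medium_conditions()] object.
#' @inheritParams ph_parameter_table
#' @return One-row tibble with the measured columns of
#'   [ph_parameter_table()] plus `d_H_nm`, `charge_C` and `charge_number`.
#' @export
#' @examples
#' parameter_set_for_ph(5.7)
parameter_set_for_ph <- function(pH, medium = medium_conditions(),
                                 d_source = c("range", "table")) {
  if (pH < 3 || pH > 11) stop("pH outside the supported range [3, 11]")
  tab <- ph_parameter_table(d_source)
  interp <- function(col) stats::approx(tab$pH, tab[[col]], xout = pH,
                                        rule = 2)$y
  row <- tibble::tibble(
    pH = pH,
    D_m2_s = interp("D_m2_s"),
    mobility_m2_Vs = interp("mobility_m2_Vs"),
    zeta_V = interp("zeta_V"),
    zeta_surface_V = interp("zeta_surface_V"))
  ch <- electrokinetic_charge(row$mobility_m2_Vs, row$D_m2_s,
                              medium$temperature)
  row$d_H_nm <- stokes_einstein_diameter(row$D_m2_s, medium)
  row$charge_C <- ch$charge_C
  row$charge_number <- ch$charge_number
  row
}

#' Define a synthetic adsorption experiment scenario
#'
#' Describes one synthetic flow-cell experiment: solution conditions,
#' technique (QCM or reflectometry), overtones, noise level and timing.
#' Defaults mirror the experimental protocol: 100 mM NaCl, 1 Hz sampling,
#' one-hour run with the rinse started at 2400 s, bulk concentration 5 mg/L
#' at flow rate 1.33e-3 cm^3/s for QCM and 1 mg/L at 1.66e-3 cm^3/s for
#' reflectometry.
#'
#' @param pH Solution pH within `[3, 11]`.
#' @param technique `"qcm"` or `"reflectometry"`.
#' @param ionic_strength Ionic strength (mol/L).
#' @param bulk_concentration Bulk concentration (mg/L).
#' @param flow_rate Volumetric flow rate (cm^3/s).
#' @param overtones Overtones synthesized for QCM scenarios.
#' @param noise_sd Standard deviation of the additive i.i.d. Gaussian
#'   measurement noise (Hz for QCM frequency shifts, mg/m^2 for
#'   reflectometry mass coverage).
#' @param seed RNG seed for the noise.
#' @param rinse_start Rinse start time (s).
#' @param duration Total duration (s).
#' @param sampling_dt Sampling interval (s).
#' @param dimeric If `TRUE`, emulate slow solution aggregation into dimers
#'   by doubling the molar mass at fixed footprint (a scenario flag, not a
#'   kinetic model of aggregation).
#' @return Object of class `experiment_scenario` (named list).
#' @export
experiment_scenario <- function(pH, technique = c("qcm", "reflectometry"),
                                ionic_strength = 0.1,
                                bulk_concentration = NULL,
                                flow_rate = NULL,
                                overtones = c(3, 5, 7, 9, 11),
                                noise_sd = NULL, seed = 1,
                                rinse_start = 2400, duration = 3600,
                                sampling_dt = 1, dimeric = FALSE) {
  technique <- match.arg(technique)
  if (pH < 3 || pH > 11) stop("pH outside the supported range [3, 11]")
  if (is.null(bulk_concentration)) {
    bulk_concentration <- if (technique == "qcm") 5 else 1
  }
  if (is.null(flow_rate)) {
    flow_rate <- if (technique == "qcm") 1.33e-3 else 1.66e-3
  }
  if (is.null(noise_sd)) noise_sd <- if (technique == "qcm") 0.1 else 0.01
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(pH = pH, technique = technique,
                 ionic_strength = ionic_strength,
                 bulk_concentration = bulk_concentration,
                 flow_rate = flow_rate, overtones = overtones,
                 noise_sd = noise_sd, seed = seed,
                 rinse_start = rinse_start, duration = duration,
                 sampling_dt = sampling_dt, dimeric = dimeric),
            class = "experiment_scenario")
}

#' Synthesize a complete adsorption experiment
#'
#' Generates the ground-truth coverage trace with [simulate_kinetics()] and
#' the corresponding measured signal: per-overtone QCM frequency shifts
#' through the forward contact model, or the mass-coverage signal itself
#' for reflectometry, with additive i.i.d. Gaussian noise. The noiseless
#' truth is stored alongside the signal so inversions can be validated
#' exactly.
#'
#' @param scenario An [experiment_scenario()].
#' @param theta_max Jamming coverage used for the truth kinetics (from
#'   [run_rsa()]/[rsa_jamming()]).
#' @param molecule A `molecule_derived` row; defaults to the PARG molecule
#'   with the reported degree of polymerisation.
#' @param transport A [transport_params()]; defaults follow the scenario's
#'   concentration, flow rate and rinse time.
#' @param params A [qcm_params()] object.
#' @param model Forward contact model for QCM scenarios.
#' @param blocking Available-surface function passed to
#'   [simulate_kinetics()]; default scaled blocking with the calibrated
#'   coefficients.
#' @param footprint Which footprint converts coverage fraction to mass:
#'   `"condensed"` or `"bare"`.
#' @return Object of class `synthetic_experiment`: list with `truth`
#'   (`kinetic_trace`), `signal` (a `qcm_trace` or a reflectometry tibble
#'   `time_s, gamma_mg_m2`), `scenario`, `model`, `molar_mass`,
#'   `footprint_nm2`, `theta_max`, `seed`.
#' @export
#' @examples
#' sc <- experiment_scenario(5.7, "qcm", duration = 600, rinse_start = 400)
#' ex <- synthesize_experiment(sc, theta_max = 0.37)
#' names(ex)
synthesize_experiment <- function(scenario, theta_max,
                                  molecule = NULL, transport = NULL,
                                  params = qcm_params(),
                                  model = c("soft", "stiff", "sauerbrey"),
                                  blocking = NULL,
                                  footprint = c("condensed", "bare")) {
  stopifnot(inherits(scenario, "experiment_scenario"))
  model <- match.arg(model)
  footprint <- match.arg(footprint)
  if (is.null(molecule)) {
    molecule <- derive_size_parameters(parg_primitives(), n_monomers = 240)
  }
  molar_mass <- attr(molecule, "primitives")$molar_mass *
    (if (scenario$dimeric) 2 else 1)
  s_g <- if (footprint == "condensed") molecule$footprint_condensed_nm2 else
    molecule$footprint_bare_nm2
  if (is.null(transport)) {
    transport <- transport_params(
      bulk_concentration = scenario$bulk_concentration,
      flow_rate = scenario$flow_rate,
      rinse_start = scenario$rinse_start)
  }
  if (is.null(blocking)) {
    blocking <- scaled_blocking_function(
      theta_max, coefficients = calibrated_blocking_coefficients())
  }
  times <- seq(0, scenario$duration, by = scenario$sampling_dt)
  truth <- simulate_kinetics(transport, blocking = blocking,
                             theta_max = theta_max, molar_mass = molar_mass,
                             footprint_nm2 = s_g, times = times)
  medium <- medium_conditions(ionic_strength = scenario$ionic_strength,
                              pH = scenario$pH)
  set.seed(scenario$seed)
  if (scenario$technique == "qcm") {
    signal <- forward_frequency_shift(truth, model = model, params = params,
                                      medium = medium,
                                      overtones = scenario$overtones)
    signal$neg_dfreq_over_n_hz <- signal$neg_dfreq_over_n_hz +
      stats::rnorm(nrow(signal), sd = scenario$noise_sd)
  } else {
    signal <- tibble::tibble(
      time_s = truth$time_s,
      gamma_mg_m2 = truth$gamma_mg_m2 +
        stats::rnorm(nrow(truth), sd = scenario$noise_sd))
  }
  structure(list(truth = truth, signal = signal, scenario = scenario,
                 model = if (scenario$technique == "qcm") model else NULL,
                 molar_mass = molar_mass, footprint_nm2 = s_g,
                 theta_max = theta_max, medium = medium, params = params,
                 seed = scenario$seed),
            class = "synthetic_experiment")
}

#' Write a synthetic experiment (truth, signal, manifest) to files
#'
#' @param experiment A `synthetic_experiment`.
#' @param dir Output directory (created if missing).
#' @param stem File-name stem.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_experiment <- function(experiment, dir, stem = "experiment") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- file.path(dir, paste0(stem, "_truth.csv"))
  signal <- file.path(dir, paste0(stem, "_signal.csv"))
  manifest <- file.path(dir, paste0(stem, "_manifest.json"))
  utils::write.csv(as.data.frame(experiment$truth), truth, row.names = FALSE)
  utils::write.csv(as.data.frame(experiment$signal), signal,
                   row.names = FALSE)
  sc <- experiment$scenario
  jsonlite::write_json(
    list(scenario = unclass(sc), model = experiment$model,
         molar_mass = experiment$molar_mass,
         footprint_nm2 = experiment$footprint_nm2,
         theta_max = experiment$theta_max, seed = experiment$seed),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(truth = truth, signal = signal, manifest = manifest))
}
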