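#' QCM sensor and adsorbate model parameters
#'
#' Constants of the quartz crystal microbalance models: sensor fundamental
#' frequency and quartz shear impedance (which fix the Sauerbrey constant),
#' adsorbate density and characteristic dimension, and the dimensionless
#' hydrodynamic constants of the stiff-contact and lubricated soft-contact
#' models.
#'
#' Defaults describe a 5 MHz AT-cut quartz sensor (`Z_q = sqrt(rho_q mu_q)
#' = 8.84e6 kg m^-2 s^-1`, giving a Sauerbrey constant of 0.177 mg m^-2
#' Hz^-1) and an elongated polyelectrolyte adsorbate of density 1500 kg/m^3
#' whose characteristic dimension is the counterion-dressed chain diameter
#' (1.4 nm). The stiff-contact constant `C_a = 9.64` holds for spherical
#' adsorbates; the soft-contact constant for the chain, `C_sc = 0.84`, is
#' the spherical-adsorbate value 1.5 reduced by the normalized hydrodynamic
#' force 0.56 of a string of touching beads.
#'
#' @param fundamental_frequency Sensor fundamental frequency `f_0` (Hz).
#' @param quartz_impedance Quartz shear impedance `Z_q` (kg m^-2 s^-1).
#' @param adsorbate_density Adsorbate density `rho_a` (kg/m^3).
#' @param adsorbate_dimension Characteristic adsorbate dimension `d_p` (nm).
#' @param stiff_constant Dimensionless stiff-contact constant `C_a`.
#' @param soft_constant Dimensionless soft-contact constant `C_sc`.
#' @param soft_sphere_constant Spherical-adsorbate soft-contact constant.
#' @param bead_force_ratio Normalized hydrodynamic force of the bead-string
#'   model relative to a sphere; `soft_constant` defaults to
#'   `soft_sphere_constant * bead_force_ratio`.
#' @param minimum_gap Minimum adsorbate-sensor distance `h_m` (nm).
#' @return Object of class `qcm_params` (named list, including the derived
#'   `sauerbrey_constant` in mg m^-2 Hz^-1).
#' @export
#' @examples
#' qcm_params()$sauerbrey_constant  # ~0.177
qcm_params <- function(fundamental_frequency = 5e6,
                       quartz_impedance = 8.84e6,
                       adsorbate_density = 1500,
                       adsorbate_dimension = 1.4,
                       stiff_constant = 9.64,
                       soft_sphere_constant = 1.5,
                       bead_force_ratio = 0.56,
                       soft_constant = soft_sphere_constant * bead_force_ratio,
                       minimum_gap = 0.5) {
  if (fundamental_frequency <= 0 || quartz_impedance < 0 ||
      adsorbate_density <= 0 || adsorbate_dimension <= 0) {
    stop("invalid QCM parameters")
  }
  structure(list(
    fundamental_frequency = fundamental_frequency,
    quartz_impedance = quartz_impedance,
    sauerbrey_constant = sauerbrey_constant(fundamental_frequency,
                                            quartz_impedance),
    adsorbate_density = adsorbate_density,
    adsorbate_dimension = adsorbate_dimension,
    stiff_constant = stiff_constant,
    soft_sphere_constant = soft_sphere_constant,
    bead_force_ratio = bead_force_ratio,
    soft_constant = soft_constant,
    minimum_gap = minimum_gap), class = "qcm_params")
}

#' Sauerbrey constant of a quartz sensor
#'
#' `C_s = Z_q / (2 f_0^2)`, converted to mg m^-2 Hz^-1.
#'
#' @param f_0 Fundamental frequency (Hz).
#' @param Z_q Quartz shear impedance (kg m^-2 s^-1).
#' @return Sauerbrey constant (mg m^-2 Hz^-1).
#' @export
#' @examples
#' sauerbrey_constant(5e6, 8.84e6)
sauerbrey_constant <- function(f_0, Z_q) {
  if (any(f_0 <= 0)) stop("f_0 must be positive")
  1e6 * Z_q / (2 * f_0^2)
}

#' Hydrodynamic penetration depth of the oscillating shear wave
#'
#' `delta = sqrt(nu / (pi n_o f_0))`: decay length of the oscillatory shear
#' flow above the sensor at overtone `n_o`.
#'
#' @param n_o Overtone number (odd integer).
#' @param f_0 Fundamental frequency (Hz).
#' @param nu Fluid kinematic viscosity (m^2/s).
#' @return Penetration depth (nm). Vectorised over `n_o`.
#' @export
#' @examples
#' penetration_depth(3)  # ~138 nm
penetration_depth <- function(n_o, f_0 = 5e6,
                              nu = medium_conditions()$kinematic_viscosity) {
  if (any(n_o <= 0) || f_0 <= 0 || nu <= 0) stop("inputs must be positive")
  1e9 * sqrt(nu / (pi * n_o * f_0))
}

#' Sauerbrey coverage from the normalized frequency shift
#'
#' `Gamma_Q = C_s * (-Delta f / n_o)`: the rigid-film (pure inertial load)
#' inversion, linear and identical for all overtones.
#'
#' @param norm_shift Normalized frequency shift `-Delta f / n_o` (Hz).
#' @param C_s Sauerbrey constant (mg m^-2 Hz^-1).
#' @return Coverage (mg/m^2). Vectorised.
#' @export
sauerbrey_coverage <- function(norm_shift, C_s = qcm_params()$sauerbrey_constant) {
  C_s * norm_shift
}

#' Normalized impedance of the stiff-contact hydrodynamic model
#'
#' Small `d_p / 2 delta` expansion of the imaginary sensor impedance
#' normalized by the pure inertial load:
#' `Z_im = 1 - C_a * (rho / rho_a) * d_p / (2 delta)`. The coverage then
#' follows from the general inversion `Gamma = C_s * (-Delta f / n_o) /
#' Z_im`, which reduces to the Sauerbrey equation as `d_p -> 0` and lies
#' slightly above it for a dilute liquid-borne adsorbate.
#'
#' @param n_o Overtone number.
#' @param params A [qcm_params()] object.
#' @param medium A [medium_conditions()] object.
#' @return Normalized imaginary impedance (dimensionless).
#' @export
stiff_impedance_factor <- function(n_o, params = qcm_params(),
                                   medium = medium_conditions()) {
  x <- params$adsorbate_dimension /
    (2 * penetration_depth(n_o, params$fundamental_frequency,
                           medium$kinematic_viscosity))
  if (any(x > 0.1)) {
    warning("d_p/(2 delta) exceeds 0.1; the small-parameter expansion of ",
            "the stiff-contact impedance loses validity")
  }
  1 - params$stiff_constant * (medium$density / params$adsorbate_density) * x
}

#' @rdname stiff_impedance_factor
#' @param norm_shift Normalized frequency shift `-Delta f / n_o` (Hz).
#' @return For `stiff_contact_coverage`: coverage (mg/m^2).
#' @export
#' @examples
#' stiff_contact_coverage(1, 3)
stiff_contact_coverage <- function(norm_shift, n_o, params = qcm_params(),
                                   medium = medium_conditions()) {
  params$sauerbrey_constant * norm_shift /
    stiff_impedance_factor(n_o, params, medium)
}

#' Lubricated soft-contact inversion of the frequency shift
#'
#' For adsorbates in lubricated (soft) contact with the sensor, free to
#' move relative to the oscillating surface through a thin fluid layer much
#' thinner than the penetration depth, the frequency response carries the
#' hydrodynamic force on top of the inertial load. The dry coverage is then
#' proportional to the Sauerbrey estimate with an overtone-independent
#' factor:
#' `Gamma = C_s * (-Delta f / n_o) / (1 + C_sc * rho / rho_a)`.
#'
#' @param norm_shift Normalized frequency shift `-Delta f / n_o` (Hz).
#' @param params A [qcm_params()] object.
#' @param medium A [medium_conditions()] object.
#' @return Coverage (mg/m^2). Vectorised.
#' @export
#' @examples
#' soft_contact_coverage(0.60 / qcm_params()$sauerbrey_constant)
soft_contact_coverage <- function(norm_shift, params = qcm_params(),
                                  medium = medium_conditions()) {
  params$sauerbrey_constant * norm_shift * soft_contact_factor(params, medium)
}

#' @rdname soft_contact_coverage
#' @export
soft_contact_factor <- function(params = qcm_params(),
                                medium = medium_conditions()) {
  1 / (1 + params$soft_constant *
         medium$density / params$adsorbate_density)
}

#' Invert a QCM trace to coverage under a chosen contact model
#'
#' @param trace Tibble with columns `time_s`, `overtone`,
#'   `neg_dfreq_over_n_hz` (and optionally `ddiss`, passed through).
#' @param model One of `"sauerbrey"`, `"stiff"`, `"soft"`.
#' @param params A [qcm_params()] object.
#' @param medium A [medium_conditions()] object.
#' @return The trace with an added `gamma_mg_m2` column.
#' @export
invert_qcm <- function(trace, model = c("sauerbrey", "stiff", "soft"),
                       params = qcm_params(), medium = medium_conditions()) {
  model <- match.arg(model)
  s <- trace$neg_dfreq_over_n_hz
  trace$gamma_mg_m2 <- switch(
    model,
    sauerbrey = sauerbrey_coverage(s, params$sauerbrey_constant),
    stiff = stiff_contact_coverage(s, trace$overtone, params, medium),
    soft = soft_contact_coverage(s, params, medium))
  trace
}

#' Forward-model QCM frequency shifts from a coverage trace
#'
#' Exact inverse of the corresponding coverage inversion: produces the
#' per-overtone normalized frequency shift that the chosen contact model
#' maps back onto the input coverage. The dissipation channel is carried
#' through as zeros (optionally noisy); no viscoelastic model is applied.
#'
#' @param trace A [simulate_kinetics()] `kinetic_trace` (or any tibble with
#'   `time_s` and `gamma_mg_m2`).
#' @param model One of `"sauerbrey"`, `"stiff"`, `"soft"`.
#' @param params A [qcm_params()] object.
#' @param medium A [medium_conditions()] object.
#' @param overtones Odd overtone numbers to synthesize.
#' @return A tibble of class `qcm_trace` with columns `time_s`, `overtone`,
#'   `neg_dfreq_over_n_hz`, `ddiss`.
#' @export
forward_frequency_shift <- function(trace,
                                    model = c("sauerbrey", "stiff", "soft"),
                                    params = qcm_params(),
                                    medium = medium_conditions(),
                                    overtones = c(3, 5, 7, 9, 11)) {
  model <- match.arg(model)
  if (any(overtones %% 2 != 1)) stop("overtones must be odd integers")
  cs <- params$sauerbrey_constant
  out <- dplyr::bind_rows(lapply(overtones, function(n) {
    shift <- switch(
      model,
      sauerbrey = trace$gamma_mg_m2 / cs,
      stiff = trace$gamma_mg_m2 * stiff_impedance_factor(n, params, medium) / cs,
      soft = trace$gamma_mg_m2 / (cs * soft_contact_factor(params, medium)))
    tibble::tibble(time_s = trace$time_s, overtone = n,
                   neg_dfreq_over_n_hz = shift, ddiss = 0)
  }))
  class(out) <- c("qcm_trace", class(out))
  out
}

#' Write a QCM trace to CSV
#'
#' @param trace A `qcm_trace`.
#' @param path Output CSV path
#'   (`time_s, overtone, neg_dfreq_over_n_hz, ddiss`).
#' @return `path`, invisibly.
#' @export
write_qcm_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
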