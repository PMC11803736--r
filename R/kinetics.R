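#' Mass coverage from the dimensionless coverage fraction
#'
#' Constitutive relation between the fractional surface coverage and the
#' adsorbed dry mass per unit area:
#' `Gamma = theta * M_n / (S_g * N_Av)`, converted to mg/m^2 with the
#' footprint in nm^2 and the molar mass in kg/mol.
#'
#' @param theta Coverage fraction(s).
#' @param molar_mass Molar mass of the molecule (kg/mol).
#' @param footprint_nm2 Side-on cross-section (footprint) area `S_g` (nm^2).
#' @return Mass coverage (mg/m^2). Vectorised over `theta`.
#' @export
#' @examples
#' coverage_mass_from_fraction(0.35, 42, 67)  # ~0.36 mg/m^2
coverage_mass_from_fraction <- function(theta, molar_mass, footprint_nm2) {
  if (any(footprint_nm2 <= 0) || molar_mass <= 0) {
    stop("molar_mass and footprint must be positive")
  }
  theta * molar_mass * 1e24 / (footprint_nm2 * .N_AV)
}

#' @rdname coverage_mass_from_fraction
#' @param gamma Mass coverage (mg/m^2).
#' @export
coverage_fraction_from_mass <- function(gamma, molar_mass, footprint_nm2) {
  gamma / coverage_mass_from_fraction(1, molar_mass, footprint_nm2)
}

#' Transport and surface-reaction parameters of a flow adsorption cell
#'
#' Parameters of the hybrid bulk/surface description: the bulk delivers
#' molecules at the mass-transfer rate `k_c` (convective diffusion), and the
#' surface boundary layer attaches them at rate `k_a B(theta)` where `B` is
#' the available-surface function. Cell geometry and flow rate are recorded
#' for bookkeeping; `k_c` subsumes them (it is obtained by calibration for a
#' given cell).
#'
#' @param k_c Bulk mass-transfer coefficient (m/s).
#' @param k_a Surface attachment coefficient (m/s).
#' @param bulk_concentration Bulk mass concentration (mg/L).
#' @param flow_rate Volumetric flow rate (cm^3/s).
#' @param cell_radius Inlet borehole radius (mm).
#' @param cell_gap Cell gap (mm).
#' @param rinse_start Time at which the inlet switches to pure electrolyte
#'   (s); `Inf` for no rinse.
#' @param desorption_rate First-order desorption rate during rinse (1/s);
#'   0 for irreversible adsorption.
#' @return Object of class `transport_params` (named list).
#' @export
transport_params <- function(k_c = 1e-7, k_a = 1e-5, bulk_concentration = 5,
                             flow_rate = 1.33e-3, cell_radius = 0.5,
                             cell_gap = 0.85, rinse_start = 2400,
                             desorption_rate = 0) {
  if (k_c < 0 || k_a < 0 || bulk_concentration < 0 || desorption_rate < 0 ||
      rinse_start < 0) {
    stop("transport parameters must be non-negative")
  }
  structure(list(k_c = k_c, k_a = k_a,
                 bulk_concentration = bulk_concentration,
                 flow_rate = flow_rate, cell_radius = cell_radius,
                 cell_gap = cell_gap, rinse_start = rinse_start,
                 desorption_rate = desorption_rate),
            class = "transport_params")
}

#' Simulate adsorption/rinse kinetics under blocking-limited transport
#'
#' Integrates the flux-matching reduction of the hybrid convective-diffusion
#' / surface-boundary-layer model. During adsorption the deposition flux is
#' the series combination of bulk transport and blocking-limited attachment,
#' `dGamma/dt = c_b k_c k_a B(theta) / (k_c + k_a B(theta))`, which reduces
#' to the transport-limited flux `k_c c_b` when `k_a B >> k_c`. At
#' `rinse_start` the bulk concentration drops to zero and the coverage
#' decays as `dGamma/dt = -k_d Gamma` (flat for irreversible adsorption,
#' `k_d = 0`).
#'
#' @param tp A [transport_params()] object.
#' @param blocking Available-surface function `B(theta)` defined on
#'   `[0, theta_max]`; see [scaled_blocking_function()]. Defaults to the
#'   Langmuir form `1 - theta / theta_max`.
#' @param theta_max Jamming (maximum) coverage fraction.
#' @param molar_mass Molar mass (kg/mol) used to convert between mass and
#'   fractional coverage.
#' @param footprint_nm2 Molecule footprint `S_g` (nm^2).
#' @param times Strictly increasing output time grid (s).
#' @param rtol Relative tolerance of the stiff-capable integrator.
#' @return A tibble of class `kinetic_trace` with columns `time_s`,
#'   `gamma_mg_m2`, `theta`, `phase` (`"adsorption"` or `"rinse"`).
#' @export
#' @examples
#' tp <- transport_params(bulk_concentration = 5, rinse_start = 2400)
#' tr <- simulate_kinetics(tp, theta_max = 0.37, molar_mass = 42,
#'                         footprint_nm2 = 67, times = seq(0, 3600, 10))
#' max(tr$gamma_mg_m2)
simulate_kinetics <- function(tp, blocking = NULL, theta_max,
                              molar_mass, footprint_nm2,
                              times = seq(0, 3600, by = 1), rtol = 1e-8) {
  stopifnot(inherits(tp, "transport_params"))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(blocking)) {
    blocking <- function(theta) pmax(0, 1 - theta / theta_max)
  }
  gamma_scale <- coverage_mass_from_fraction(1, molar_mass, footprint_nm2)
  gamma_max <- theta_max * gamma_scale
  c_b <- tp$bulk_concentration * 1e3          # mg/L -> mg/m^3

  deriv <- function(t, y, parms) {
    gamma <- min(y[1], gamma_max)
    if (t < tp$rinse_start) {
      theta <- gamma / gamma_scale
      b <- max(0, blocking(min(theta, theta_max)))
      denom <- tp$k_c + tp$k_a * b
      flux <- if (denom > 0) c_b * tp$k_c * tp$k_a * b / denom else 0
      list(flux)
    } else {
      list(-tp$desorption_rate * gamma)
    }
  }
  # integrate the two phases separately so the discontinuity at rinse_start
  # never sits inside an integrator step
  t_ads <- times[times <= tp$rinse_start]
  t_rin <- times[times > tp$rinse_start]
  run <- function(tgrid, y0) {
    if (length(tgrid) < 2) {
      return(matrix(c(tgrid, rep(y0, length(tgrid))), ncol = 2))
    }
    deSolve::ode(y = c(gamma = y0), times = tgrid, func = deriv,
                 parms = NULL, method = "lsoda", rtol = rtol,
                 atol = 1e-12)[, 1:2]
  }
  out1 <- run(unique(c(t_ads, if (length(t_rin)) tp$rinse_start)), 0)
  g_rinse0 <- out1[nrow(out1), 2]
  keep1 <- out1[, 1] %in% t_ads
  res <- tibble::tibble(time_s = out1[keep1, 1],
                        gamma_mg_m2 = pmin(out1[keep1, 2], gamma_max),
                        phase = "adsorption")
  if (length(t_rin)) {
    out2 <- run(unique(c(tp$rinse_start, t_rin)), g_rinse0)
    keep2 <- out2[, 1] %in% t_rin
    res <- dplyr::bind_rows(res, tibble::tibble(
      time_s = out2[keep2, 1],
      gamma_mg_m2 = pmin(out2[keep2, 2], gamma_max),
      phase = "rinse"))
  }
  res$theta <- res$gamma_mg_m2 / gamma_scale
  res <- res[, c("time_s", "gamma_mg_m2", "theta", "phase")]
  attr(res, "gamma_scale") <- gamma_scale
  attr(res, "theta_max") <- theta_max
  class(res) <- c("kinetic_trace", class(res))
  res
}

#' Write a kinetic trace to CSV
#'
#' @param trace A `kinetic_trace`.
#' @param path Output CSV path (`time_s, gamma_mg_m2, theta, phase`).
#' @return `path`, invisibly.
#' @export
write_kinetic_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
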