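#' Streaming-current slope from a pressure/current series
#'
#' Fits the streaming current `I` versus the applied hydrostatic pressure
#' difference `dp` by least squares through the origin, as the streaming
#' current vanishes at zero pressure difference.
#'
#' @param data Data frame with the pressure and current columns.
#' @param pressure_col,current_col Column names (Pa, A).
#' @return The slope `dI/dp` (A/Pa).
#' @export
#' @examples
#' d <- data.frame(pressure_Pa = 1:5 * 100, current_A = 1:5 * 2e-8)
#' streaming_slope(d)
streaming_slope <- function(data, pressure_col = "pressure_Pa",
                            current_col = "current_A") {
  p <- data[[pressure_col]]
  i <- data[[current_col]]
  if (is.null(p) || is.null(i)) stop("pressure/current columns not found")
  sum(p * i) / sum(p * p)
}

#' Zeta potential from the streaming-current slope
#'
#' Helmholtz-Smoluchowski relationship for a slit channel:
#' `zeta = eta * L / (eps * S_c) * dI/dp`. The sign of the slope is
#' preserved, so a negative streaming-current slope yields a negative
#' surface zeta potential.
#'
#' @param slope Streaming-current slope `dI/dp` (A/Pa).
#' @param channel_length Channel length `L` (m).
#' @param cross_section Channel cross-section area `S_c` (m^2).
#' @param medium A [medium_conditions()] object.
#' @return Zeta potential (V). Vectorised over `slope`.
#' @export
zeta_from_streaming <- function(slope, channel_length, cross_section,
                                medium = medium_conditions()) {
  if (channel_length <= 0 || cross_section <= 0) {
    stop("channel geometry must be strictly positive")
  }
  medium$viscosity * channel_length * slope /
    (medium$permittivity * cross_section)
}

#' Hydrodynamic diameter from the diffusion coefficient
#'
#' Stokes-Einstein relationship `d_H = k T / (3 pi eta D)`.
#'
#' @param diffusion_coefficient Diffusion coefficient (m^2/s).
#' @param medium A [medium_conditions()] object.
#' @return Hydrodynamic diameter (nm). Vectorised.
#' @export
#' @examples
#' stokes_einstein_diameter(4.5e-11)  # ~11 nm
stokes_einstein_diameter <- function(diffusion_coefficient,
                                     medium = medium_conditions()) {
  if (any(diffusion_coefficient <= 0)) {
    stop("diffusion coefficient must be positive")
  }
  1e9 * .kB * medium$temperature /
    (3 * pi * medium$viscosity * diffusion_coefficient)
}

#' Electrokinetic charge from mobility and diffusivity
#'
#' Lorentz-Stokes formula `q_e = k T mu_e / D`, valid for arbitrary charge
#' distributions and molecular shapes as long as the double-layer thickness
#' stays small compared to the chain diameter. The number of elementary
#' charges is `N_c = q_e / e`.
#'
#' @param mobility Electrophoretic mobility (m^2 V^-1 s^-1).
#' @param diffusion_coefficient Diffusion coefficient (m^2/s).
#' @param temperature Absolute temperature (K).
#' @return A [tibble::tibble()] with `charge_C` and `charge_number`.
#' @export
#' @examples
#' electrokinetic_charge(2.7e-8, 4.5e-11)  # N_c ~ 15
electrokinetic_charge <- function(mobility, diffusion_coefficient,
                                  temperature = 298) {
  if (any(diffusion_coefficient <= 0)) {
    stop("diffusion coefficient must be positive")
  }
  q <- .kB * temperature * mobility / diffusion_coefficient
  tibble::tibble(charge_C = q, charge_number = q / .e_charge)
}
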