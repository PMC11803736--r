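#' Electrolyte medium conditions
#'
#' Temperature and fluid properties of the electrolyte. Defaults are water
#' with 100 mM NaCl at 298 K: dynamic viscosity 0.89e-3 Pa s, kinematic
#' viscosity 0.893e-6 m^2/s, permittivity 6.95e-10 F/m, density 997 kg/m^3.
#'
#' @param temperature Absolute temperature (K).
#' @param viscosity Dynamic viscosity (Pa s).
#' @param kinematic_viscosity Kinematic viscosity (m^2/s); must agree with
#'   `viscosity / density` within 1%.
#' @param permittivity Electric permittivity of the electrolyte (F/m).
#' @param density Fluid density (kg/m^3).
#' @param ionic_strength Ionic strength (mol/L), 1:1 electrolyte.
#' @param pH Solution pH.
#' @return An object of class `medium_conditions` (named list).
#' @export
#' @examples
#' medium_conditions()
medium_conditions <- function(temperature = 298, viscosity = 0.89e-3,
                              kinematic_viscosity = 0.893e-6,
                              permittivity = 6.95e-10, density = 997,
                              ionic_strength = 0.1, pH = 5.7) {
  if (temperature <= 0 || viscosity <= 0 || kinematic_viscosity <= 0 ||
      permittivity <= 0 || density <= 0) {
    stop("medium properties must be strictly positive")
  }
  if (abs(kinematic_viscosity - viscosity / density) >
      0.01 * kinematic_viscosity) {
    stop("kinematic_viscosity must equal viscosity / density within 1%")
  }
  structure(list(temperature = temperature, viscosity = viscosity,
                 kinematic_viscosity = kinematic_viscosity,
                 permittivity = permittivity, density = density,
                 ionic_strength = ionic_strength, pH = pH),
            class = "medium_conditions")
}

#' Debye screening length of a 1:1 electrolyte
#'
#' `kappa^-1 = sqrt(eps k T / (2e3 N_Av e^2 I))` with the ionic strength
#' `I` in mol/L. For water at 298 K this is the familiar `0.304 / sqrt(I)`
#' nm rule.
#'
#' @param ionic_strength Ionic strength (mol/L); defaults to the medium's.
#' @param medium A [medium_conditions()] object.
#' @return Debye length (nm).
#' @export
#' @examples
#' debye_length(0.1)  # ~0.96 nm
debye_length <- function(ionic_strength = medium$ionic_strength,
                         medium = medium_conditions()) {
  if (any(ionic_strength <= 0)) stop("ionic_strength must be positive")
  kappa2 <- 2 * 1e3 * .N_AV * .e_charge^2 * ionic_strength /
    (medium$permittivity * .kB * medium$temperature)
  1e9 / sqrt(kappa2)
}
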