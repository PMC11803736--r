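# Physical constants (SI, CODATA)
.kB <- 1.380649e-23     # Boltzmann constant [J/K]
.N_AV <- 6.02214076e23  # Avogadro number [1/mol]
.e_charge <- 1.602176634e-19  # elementary charge [C]

#' Physical constants used throughout the package
#'
#' Returns the Boltzmann constant, the Avogadro number and the elementary
#' charge as a named list (SI units). Exposed so that scripts can echo the
#' constants they rely on instead of hard-coding them.
#'
#' @return Named list with `k_B` (J/K), `N_Av` (1/mol) and `e` (C).
#' @export
#' @examples
#' physical_constants()$k_B
physical_constants <- function() {
  list(k_B = .kB, N_Av = .N_AV, e = .e_charge)
}
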