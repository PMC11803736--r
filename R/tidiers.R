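#' Tidy an RSA result into its particle configuration
#'
#' @param x An `rsa_result`.
#' @param ... Unused.
#' @return Tibble with one row per adsorbed particle
#'   (`x_nm, y_nm, theta_rad, L_nm, d_nm`).
#' @export
tidy.rsa_result <- function(x, ...) x$particles

#' One-row summary of an RSA run
#'
#' @param x An `rsa_result`.
#' @param ... Unused.
#' @return One-row tibble: `accepted`, `attempts`, `final_coverage`,
#'   `jamming_coverage`, `box_side`, `particle_length`,
#'   `particle_diameter`, `aspect_ratio`.
#' @export
glance.rsa_result <- function(x, ...) {
  tibble::tibble(
    accepted = x$accepted,
    attempts = x$attempts,
    final_coverage = x$final_coverage,
    jamming_coverage = x$jamming_coverage,
    box_side = x$box_side,
    particle_length = x$effective$total_length,
    particle_diameter = x$effective$diameter,
    aspect_ratio = x$effective$total_length / x$effective$diameter)
}

#' One-row summary of a kinetic trace
#'
#' @param x A `kinetic_trace`.
#' @param ... Unused.
#' @return One-row tibble: plateau coverage (mass and fraction, taken at
#'   the end of the adsorption phase), final coverage after rinse, and the
#'   rinse retention ratio.
#' @export
glance.kinetic_trace <- function(x, ...) {
  ads <- x[x$phase == "adsorption", ]
  plateau <- ads$gamma_mg_m2[nrow(ads)]
  final <- x$gamma_mg_m2[nrow(x)]
  tibble::tibble(
    plateau_gamma_mg_m2 = plateau,
    plateau_theta = ads$theta[nrow(ads)],
    final_gamma_mg_m2 = final,
    rinse_retention = if (plateau > 0) final / plateau else NA_real_)
}

#' @export
print.rsa_result <- function(x, ...) {
  cat("<rsa_result>\n")
  cat(sprintf("  particles: %d accepted in %.3g attempts (box %.4g nm)\n",
              x$accepted, x$attempts, x$box_side))
  cat(sprintf("  coverage: final %.4f, jamming estimate %.4f\n",
              x$final_coverage, x$jamming_coverage))
  invisible(x)
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  sc <- x$scenario
  cat("<synthetic_experiment>\n")
  cat(sprintf("  %s at pH %.1f, c_b = %g mg/L, noise sd %g\n",
              sc$technique, sc$pH, sc$bulk_concentration, sc$noise_sd))
  cat(sprintf("  theta_max %.3f -> plateau %.3f mg/m^2\n", x$theta_max,
              max(x$truth$gamma_mg_m2)))
  invisible(x)
}
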