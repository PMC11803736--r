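# Calibration constants for the electrostatic equivalent-hard-particle
# enlargement and the blocking-function shape coefficients. Values frozen by
# scripts/calibrate_rsa.R (see the methods vignette); overridable per call.
.phi0_prefactor_default <- 0.58
.blocking_coefficients_calibrated <- c(a1 = 24.151, a2 = 0)

#' Overlap test for two spherocylinders on a periodic box
#'
#' Two spherocylinders overlap iff the minimum distance between their axis
#' segments (under the minimum-image convention) is smaller than the mean of
#' their diameters.
#'
#' @param a,b Named lists/vectors with `x`, `y` (box units, nm), `theta`
#'   (radians), `length` (axis length excluding caps, nm) and `diameter`
#'   (nm).
#' @param box_side Side of the periodic square box (nm).
#' @return `TRUE` if the particles overlap.
#' @export
#' @examples
#' p <- list(x = 0, y = 0, theta = 0, length = 10, diameter = 1)
#' q <- list(x = 0, y = 2, theta = 0, length = 10, diameter = 1)
#' spherocylinders_overlap(p, q, 100)
spherocylinders_overlap <- function(a, b, box_side) {
  d <- .segment_min_dist(c(a$x, a$y, a$theta, a$length),
                         c(b$x, b$y, b$theta, b$length), box_side)
  d < (a$diameter + b$diameter) / 2
}

#' Random sequential adsorption of spherocylinders on a periodic plane
#'
#' Places congruent spherocylinders at uniformly random positions and
#' orientations on a periodic square box; a trial particle is accepted iff
#' it overlaps no previously adsorbed particle (irreversible, localized
#' adsorption). The run stops at `max_attempts` or when `stop_attempts`
#' trials pass without a success. The jamming coverage is estimated by
#' extrapolating the tail of the coverage trajectory with the asymptotic
#' power law `theta(tau) = theta_mx - c * tau^(-extrapolation_exponent)`.
#'
#' Electrostatic repulsion between like-charged molecules is represented by
#' the equivalent-hard-particle approach: pass `effective` (see
#' [effective_dimensions()]) to use enlarged dimensions in the overlap test
#' while the reported coverage still counts the physical footprint
#' `shape$area`.
#'
#' @param shape A [spherocylinder_shape()]: the physical particle.
#' @param effective Optional [spherocylinder_shape()] with the enlarged
#'   (interaction) dimensions; defaults to `shape`.
#' @param box_side Side of the periodic box (nm); default 20 times the
#'   effective tip-to-tip length, and at least 10 times is required.
#' @param max_attempts Maximum number of placement attempts.
#' @param stop_attempts Stop once this many consecutive attempts fail.
#' @param seed Integer seed for the run (`set.seed`); `NULL` continues the
#'   current RNG stream.
#' @param extrapolation_exponent Tail exponent; 1/3 for particles with three
#'   degrees of freedom (x, y, orientation), 1/2 for disks.
#' @param tail_fraction The tail fit uses trajectory points with
#'   dimensionless time greater than `tail_fraction` times its final value.
#' @param probe_thetas Optional coverages at which the available-surface
#'   (blocking) function is measured by ghost insertions.
#' @param probe_trials Number of ghost insertions per probe.
#' @param n_windows Number of uniform attempt windows for the windowed
#'   acceptance bookkeeping.
#'
#' @return An object of class `rsa_result`: list with `particles` (tibble
#'   `x_nm, y_nm, theta_rad, L_nm, d_nm`), `trajectory` (tibble `attempt,
#'   time, coverage`; `time` is the dimensionless time `attempts *
#'   shape$area / box_side^2`), `jamming_coverage`, `blocking` (tibble
#'   `theta, B` from the probes), `final_coverage`, `attempts`, `box_side`,
#'   `shape`, `effective`.
#' @export
#' @examples
#' r <- run_rsa(spherocylinder_shape(1, 1), box_side = 15,
#'              max_attempts = 2e4, seed = 1, extrapolation_exponent = 1/2)
#' r$final_coverage
run_rsa <- function(shape, effective = NULL, box_side = NULL,
                    max_attempts = 1e7, stop_attempts = Inf, seed = NULL,
                    extrapolation_exponent = 1 / 3, tail_fraction = 0.1,
                    probe_thetas = NULL, probe_trials = 1e6,
                    n_windows = 200) {
  stopifnot(inherits(shape, "spherocylinder_shape"))
  eff <- if (is.null(effective)) shape else effective
  stopifnot(inherits(eff, "spherocylinder_shape"))
  if (is.null(box_side)) box_side <- 20 * eff$total_length
  if (box_side < 10 * eff$total_length) {
    stop("box_side must be at least 10 effective particle lengths")
  }
  if (max_attempts <= 0) stop("max_attempts must be positive")
  if (!is.null(seed)) set.seed(seed)

  probe_counts <- integer(0)
  if (!is.null(probe_thetas)) {
    probe_counts <- unique(as.integer(round(
      probe_thetas * box_side^2 / shape$area)))
  }
  k <- .rsa_kernel(eff$length, eff$diameter, box_side, max_attempts,
                   stop_attempts, as.integer(n_windows),
                   probe_counts, probe_trials)
  n <- length(k$x)
  a_norm <- shape$area / box_side^2
  traj <- tibble::tibble(attempt = k$success_attempt,
                         time = k$success_attempt * a_norm,
                         coverage = seq_len(n) * a_norm)
  jam <- jamming_extrapolation(traj, exponent = extrapolation_exponent,
                               tail_fraction = tail_fraction)
  blocking <- tibble::tibble(theta = k$probe_count * a_norm,
                             B = k$probe_acceptance)
  structure(list(
    particles = tibble::tibble(x_nm = k$x, y_nm = k$y, theta_rad = k$theta,
                               L_nm = eff$length, d_nm = eff$diameter),
    trajectory = traj,
    jamming_coverage = jam,
    blocking = blocking,
    final_coverage = n * a_norm,
    accepted = n,
    attempts = k$attempts,
    window_attempts = k$window_attempts,
    window_accepted = k$window_accepted,
    box_side = box_side,
    shape = shape,
    effective = eff,
    seed = seed,
    extrapolation_exponent = extrapolation_exponent),
    class = "rsa_result")
}

#' Extrapolate a coverage trajectory to the jamming limit
#'
#' Linear fit of coverage against `time^(-exponent)` over the late-time tail
#' (`time > max(time) * tail_fraction`); the intercept estimates the jamming
#' coverage.
#'
#' @param trajectory Tibble with `time` and `coverage` columns.
#' @param exponent Asymptotic relaxation exponent.
#' @param tail_fraction Start of the fitted tail as a fraction of the final
#'   dimensionless time.
#' @return Estimated jamming coverage.
#' @export
jamming_extrapolation <- function(trajectory, exponent = 1 / 3,
                                  tail_fraction = 0.1) {
  keep <- trajectory$time > max(trajectory$time) * tail_fraction
  if (sum(keep) < 10) return(max(trajectory$coverage))
  fit <- stats::lm(coverage ~ I(time^(-exponent)),
                   data = trajectory[keep, ])
  unname(stats::coef(fit)[1])
}

#' Jamming coverage averaged over independent RSA runs
#'
#' Runs [run_rsa()] for several seeds and reports the mean jamming coverage
#' with its standard error.
#'
#' @inheritParams run_rsa
#' @param seeds Integer vector of seeds (at least 3 recommended).
#' @param ... Passed to [run_rsa()].
#' @return A list with `mean`, `se`, and `per_seed` (tibble `seed,
#'   jamming_coverage, final_coverage`).
#' @export
rsa_jamming <- function(shape, seeds = 1:3, ...) {
  runs <- lapply(seeds, function(s) run_rsa(shape, seed = s, ...))
  per <- tibble::tibble(
    seed = seeds,
    jamming_coverage = vapply(runs, `[[`, numeric(1), "jamming_coverage"),
    final_coverage = vapply(runs, `[[`, numeric(1), "final_coverage"))
  list(mean = mean(per$jamming_coverage),
       se = stats::sd(per$jamming_coverage) / sqrt(length(seeds)),
       per_seed = per)
}

#' Scaled-particle-theory shape coefficients of a convex 2D particle
#'
#' For an isotropic fluid of congruent hard convex particles of area `A`
#' and perimeter `P`, scaled particle theory gives the insertion probability
#' [spt_blocking_function()] with `a1 = 1 + P^2 / (2 pi A)` and
#' `a2 = P^2 / (4 pi A)`. For disks these reduce to `a1 = 3`, `a2 = 1`, and
#' the low-coverage expansion `B = 1 - 4 theta + O(theta^2)` recovers the
#' excluded area of two disks (four particle areas).
#'
#' Equilibrium scaled particle theory describes the acceptance probability
#' of a random sequential adsorption process only at low coverage; for
#' strongly elongated particles the coefficients fitted to the measured
#' acceptance ([calibrated_blocking_coefficients()]) should be preferred at
#' moderate coverage.
#'
#' @param shape A [spherocylinder_shape()].
#' @return Named vector `c(a1, a2)`.
#' @export
#' @examples
#' spt_coefficients(spherocylinder_shape(1, 1))  # disk: a1 = 3, a2 = 1
spt_coefficients <- function(shape) {
  stopifnot(inherits(shape, "spherocylinder_shape"))
  a <- shape$area
  p <- 2 * shape$length + pi * shape$diameter
  c(a1 = 1 + p^2 / (2 * pi * a), a2 = p^2 / (4 * pi * a))
}

#' Blocking coefficients calibrated against the measured acceptance
#'
#' Shape coefficients of [spt_blocking_function()] fitted (by
#' `scripts/calibrate_rsa.R`) to the ghost-insertion acceptance probability
#' of the reference adsorbing molecule: a spherocylinder of tip-to-tip
#' length 48 nm and diameter 1.4 nm (aspect ratio approximately 34). The
#' fit minimises the worst-case log-domain residual over the pre-jamming
#' range subject to `a1, a2 >= 0`, the condition under which the SPT form
#' is a strictly decreasing insertion probability on `[0, 1)` (required by
#' the kinetics solver). They track the measured available-surface function
#' of that shape far more closely than the equilibrium coefficients of
#' [spt_coefficients()], but the constrained two-coefficient family still
#' deviates by up to a factor of about two near jamming; see the methods
#' vignette for the residual analysis.
#'
#' @return Named vector `c(a1, a2)`.
#' @export
calibrated_blocking_coefficients <- function() {
  .blocking_coefficients_calibrated
}

#' Scaled-particle-theory available-surface (blocking) function
#'
#' Probability that a placement attempt succeeds at coverage `theta`:
#' `B(theta) = (1 - theta) * exp(-a1 * x - a2 * x^2)` with
#' `x = theta / (1 - theta)`. `B(0) = 1` and `B` decreases strictly to 0 at
#' `theta = 1`.
#'
#' @param theta Coverage fraction(s), in `[0, 1)`.
#' @param shape A [spherocylinder_shape()] used to compute the default
#'   coefficients; ignored when `coefficients` is given.
#' @param coefficients Named vector `c(a1, a2)`; defaults to
#'   [spt_coefficients()] of `shape`.
#' @return Blocking function value(s).
#' @export
#' @examples
#' spt_blocking_function(0.2, spherocylinder_shape(1, 1))
spt_blocking_function <- function(theta, shape = NULL, coefficients = NULL) {
  if (any(theta < 0 | theta >= 1)) stop("theta must lie in [0, 1)")
  if (is.null(coefficients)) {
    if (is.null(shape)) stop("provide either shape or coefficients")
    coefficients <- spt_coefficients(shape)
  }
  x <- theta / (1 - theta)
  (1 - theta) * exp(-coefficients[["a1"]] * x - coefficients[["a2"]] * x^2)
}

#' Blocking function rescaled to a finite jamming coverage
#'
#' Maps the coverage onto `theta / theta_max` before evaluating
#' [spt_blocking_function()], so that the returned function vanishes at the
#' jamming coverage `theta_max` rather than at unity. This is the form used
#' by the adsorption-kinetics solver.
#'
#' @param theta_max Jamming coverage.
#' @param shape,coefficients Passed to [spt_blocking_function()].
#' @return A function of `theta`.
#' @export
scaled_blocking_function <- function(theta_max, shape = NULL,
                                     coefficients = NULL) {
  if (theta_max <= 0 || theta_max >= 1) stop("theta_max must be in (0, 1)")
  force(shape); force(coefficients)
  function(theta) {
    x <- pmin(pmax(theta / theta_max, 0), 1 - 1e-12)
    spt_blocking_function(x, shape = shape, coefficients = coefficients)
  }
}

#' Electrostatic equivalent-hard-particle dimensions
#'
#' Represents the soft lateral repulsion between adsorbed like-charged
#' molecules by enlarging the hard particle with the effective interaction
#' range `h*`, obtained from the screened-Coulomb (Yukawa) pair interaction:
#' `h* = (kappa^-1 / 2) * ln(phi0 / kT)` clamped at zero, where the contact
#' energy is `phi0 = prefactor * pi * eps * d * zeta^2` for chains of
#' diameter `d` at molecule zeta potential `zeta`. Both the effective length
#' and diameter grow by `2 h*`.
#'
#' The dimensionless `prefactor` absorbs the geometry factors of the exact
#' pair interaction between adsorbed chains; its default is calibrated by
#' `scripts/calibrate_rsa.R` against the pH trend of the maximum coverage
#' (see the methods vignette).
#'
#' @param shape A [spherocylinder_shape()]: the physical molecule.
#' @param zeta_molecule Molecule zeta potential (V).
#' @param zeta_surface Substrate zeta potential (V); carried for
#'   bookkeeping (it controls adhesion, not the lateral blocking) and not
#'   used in `h*`.
#' @param medium A [medium_conditions()] object (Debye length, permittivity,
#'   temperature).
#' @param prefactor Dimensionless contact-energy prefactor.
#' @return A list of class `effective_particle` with `h_star` (nm),
#'   `shape` (the enlarged [spherocylinder_shape()]), `phi0_kT` (contact
#'   energy in units of kT) and the inputs.
#' @export
#' @examples
#' sh <- spherocylinder_shape(48, 1.4)
#' effective_dimensions(sh, zeta_molecule = 0.049)
effective_dimensions <- function(shape, zeta_molecule, zeta_surface = NULL,
                                 medium = medium_conditions(),
                                 prefactor = .phi0_prefactor_default) {
  stopifnot(inherits(shape, "spherocylinder_shape"))
  kT <- .kB * medium$temperature
  phi0 <- prefactor * pi * medium$permittivity *
    (shape$diameter * 1e-9) * zeta_molecule^2
  kappa_inv <- debye_length(medium$ionic_strength, medium)
  h_star <- max(0, kappa_inv / 2 * log(phi0 / kT))
  eff <- spherocylinder_shape(shape$total_length + 2 * h_star,
                              shape$diameter + 2 * h_star)
  structure(list(h_star = h_star, shape = eff, phi0_kT = phi0 / kT,
                 kappa_inv_nm = kappa_inv, zeta_molecule = zeta_molecule,
                 zeta_surface = zeta_surface, prefactor = prefactor),
            class = "effective_particle")
}

#' Write an RSA configuration or trajectory to CSV
#'
#' @param result An `rsa_result`.
#' @param particles_path,trajectory_path Output CSV paths (either may be
#'   `NULL` to skip).
#' @return `result`, invisibly.
#' @export
write_rsa_csv <- function(result, particles_path = NULL,
                          trajectory_path = NULL) {
  if (!is.null(particles_path)) {
    utils::write.csv(result$particles, particles_path, row.names = FALSE)
  }
  if (!is.null(trajectory_path)) {
    utils::write.csv(result$trajectory[, c("attempt", "coverage")],
                     trajectory_path, row.names = FALSE)
  }
  invisible(result)
}
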