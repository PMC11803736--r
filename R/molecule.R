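#' Molecular-dynamics chain primitives of a polyelectrolyte molecule
#'
#' Bundles the primitive single-chain quantities that an all-atom MD
#' simulation (or equivalent characterisation) provides for a linear
#' polyelectrolyte: monomer length, bare chain diameter, chain diameter with
#' condensed counterions, and reference end-to-end distance / radius of
#' gyration at a reference degree of polymerisation. All geometry derived by
#' [derive_size_parameters()] starts from these numbers plus the molar mass
#' and bulk density.
#'
#' @param molar_mass Number-average molar mass of the chain (kg/mol).
#' @param monomer_molar_mass Molar mass of one repeat unit (kg/mol).
#' @param density Bulk density of the polymer (kg/m^3).
#' @param monomer_length Contour length contributed by one monomer (nm).
#' @param bare_diameter Bare chain diameter (nm).
#' @param condensed_diameter Chain diameter including the layer of condensed
#'   counterions (nm); must be at least `bare_diameter`.
#' @param ete_ref Average end-to-end distance at the reference degree of
#'   polymerisation (nm).
#' @param rg_ref Average radius of gyration at the reference degree of
#'   polymerisation (nm).
#' @param n_ref Reference number of monomers at which `ete_ref` and `rg_ref`
#'   were obtained.
#'
#' @return An object of class `molecule_primitives` (named list).
#' @seealso [parg_primitives()] for the poly-L-arginine defaults.
#' @export
molecule_primitives <- function(molar_mass, monomer_molar_mass, density,
                                monomer_length, bare_diameter,
                                condensed_diameter, ete_ref = NA_real_,
                                rg_ref = NA_real_, n_ref = NA_real_) {
  p <- list(molar_mass = molar_mass, monomer_molar_mass = monomer_molar_mass,
            density = density, monomer_length = monomer_length,
            bare_diameter = bare_diameter,
            condensed_diameter = condensed_diameter,
            ete_ref = ete_ref, rg_ref = rg_ref, n_ref = n_ref)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L, logical(1))
  if (!all(num)) stop("all primitives must be single numeric values")
  pos <- c("molar_mass", "monomer_molar_mass", "density", "monomer_length",
           "bare_diameter", "condensed_diameter")
  if (any(unlist(p[pos]) <= 0)) {
    stop("molecule primitives must be strictly positive")
  }
  if (condensed_diameter < bare_diameter) {
    stop("condensed_diameter must be >= bare_diameter")
  }
  if (molar_mass < monomer_molar_mass) {
    stop("molar_mass must be >= monomer_molar_mass")
  }
  structure(p, class = "molecule_primitives")
}

#' Poly-L-arginine (PARG) chain primitives
#'
#' MD-derived primitives for a 42 kg/mol poly-L-arginine chain in 100 mM
#' NaCl at 298 K: monomer length 0.20 nm, bare chain diameter 1.1 nm,
#' diameter with condensed counterions 1.4 nm, and end-to-end distance /
#' radius of gyration of 9.88 and 3.50 nm for the 50-mer reference chain.
#'
#' @return A [molecule_primitives()] object.
#' @export
#' @examples
#' derive_size_parameters(parg_primitives(), n_monomers = 240)
parg_primitives <- function() {
  molecule_primitives(
    molar_mass = 42, monomer_molar_mass = 0.174, density = 1500,
    monomer_length = 0.20, bare_diameter = 1.1, condensed_diameter = 1.4,
    ete_ref = 9.88, rg_ref = 3.50, n_ref = 50)
}

#' Derive secondary molecular geometry from chain primitives
#'
#' Computes the full set of derived single-molecule quantities from the MD
#' primitives: monomer count, molecular volume, equivalent sphere diameter,
#' contour length, equivalent cylinder length, aspect ratio, side-on
#' footprint areas and the chain metrics extrapolated to the experimental
#' degree of polymerisation.
#'
#' The monomer count defaults to the exact mass ratio `M_n / M_1`. Published
#' characterisation of a given sample often quotes a rounded degree of
#' polymerisation (240 for the 42 kg/mol poly-L-arginine studied here); pass
#' it through `n_monomers` to reproduce tabulated values that were computed
#' with the rounded count.
#'
#' The equivalent cylinder length is obtained by recasting the molecular
#' volume as a cylinder of the *bare* chain diameter, `L_e = 4 v_p / (pi
#' d_b^2)`; the aspect ratio then uses the diameter with condensed
#' counterions, `lambda = L_e / d_c`.
#'
#' @param p A [molecule_primitives()] object.
#' @param n_monomers Optional monomer count overriding the exact ratio
#'   `molar_mass / monomer_molar_mass` (e.g. a reported degree of
#'   polymerisation).
#'
#' @return A one-row [tibble::tibble()] of class `molecule_derived` with
#'   columns `n_monomers`, `volume_nm3`, `sphere_diameter_nm`,
#'   `contour_length_nm`, `cylinder_length_nm`, `aspect_ratio`,
#'   `footprint_bare_nm2`, `footprint_condensed_nm2`, `ete_nm`, `rg_nm`.
#'   The primitives are attached as attribute `primitives`.
#' @export
#' @examples
#' derive_size_parameters(parg_primitives())
derive_size_parameters <- function(p, n_monomers = NULL) {
  stopifnot(inherits(p, "molecule_primitives"))
  n_m <- if (is.null(n_monomers)) p$molar_mass / p$monomer_molar_mass else n_monomers
  if (n_m <= 0) stop("monomer count must be positive")
  v_p <- 1e27 * p$molar_mass / (p$density * .N_AV)       # nm^3
  d_sphere <- (6 * v_p / pi)^(1 / 3)                     # nm
  contour <- n_m * p$monomer_length                      # nm
  l_e <- 4 * v_p / (pi * p$bare_diameter^2)              # nm
  lambda <- l_e / p$condensed_diameter
  ete <- if (is.na(p$ete_ref)) NA_real_ else
    scale_chain_metric(p$ete_ref, p$n_ref, n_m)
  rg <- if (is.na(p$rg_ref)) NA_real_ else
    scale_chain_metric(p$rg_ref, p$n_ref, n_m)
  out <- tibble::tibble(
    n_monomers = n_m,
    volume_nm3 = v_p,
    sphere_diameter_nm = d_sphere,
    contour_length_nm = contour,
    cylinder_length_nm = l_e,
    aspect_ratio = lambda,
    footprint_bare_nm2 = footprint_area(contour, p$bare_diameter),
    footprint_condensed_nm2 = footprint_area(contour, p$condensed_diameter),
    ete_nm = ete,
    rg_nm = rg)
  attr(out, "primitives") <- p
  class(out) <- c("molecule_derived", class(out))
  out
}

#' Side-on footprint area of a spherocylinder
#'
#' Area of the 2D projection of a rod with rounded ends lying flat on the
#' surface: a rectangle `(contour - d) * d` plus the two half-disk caps
#' `pi d^2 / 4`. A zero-length rod (`contour == d`) degenerates to a disk.
#'
#' @param contour_length Tip-to-tip length of the molecule (nm).
#' @param diameter Chain diameter (nm).
#' @return Footprint area (nm^2). Vectorised over both arguments.
#' @export
#' @examples
#' footprint_area(48, 1.1)  # bare chain, ~53 nm^2
#' footprint_area(48, 1.4)  # with condensed counterions, ~67 nm^2
footprint_area <- function(contour_length, diameter) {
  if (any(diameter <= 0)) stop("diameter must be positive")
  if (any(contour_length < diameter)) {
    stop("contour_length must be >= diameter")
  }
  (contour_length - diameter) * diameter + pi * diameter^2 / 4
}

#' Linearly extrapolate a chain metric to another degree of polymerisation
#'
#' For strongly elongated chains (aspect ratio much greater than 1) the
#' end-to-end distance and radius of gyration scale essentially linearly
#' with the number of monomers, so a reference value at `n_ref` monomers is
#' rescaled by `n_target / n_ref` (scaling exponent 1).
#'
#' @param value_ref Metric at the reference chain length (nm).
#' @param n_ref Reference monomer count.
#' @param n_target Target monomer count.
#' @return The extrapolated metric (nm). Vectorised.
#' @export
#' @examples
#' scale_chain_metric(9.88, 50, 240)  # end-to-end distance, ~47.4 nm
scale_chain_metric <- function(value_ref, n_ref, n_target) {
  if (any(n_ref <= 0)) stop("n_ref must be positive")
  value_ref * n_target / n_ref
}

#' Spherocylinder shape template of an adsorbing molecule
#'
#' Converts derived molecular geometry into the 2D spherocylinder template
#' placed by [run_rsa()]: the tip-to-tip length equals the contour length
#' and the width equals the chosen chain diameter.
#'
#' @param derived A `molecule_derived` row from [derive_size_parameters()].
#' @param diameter Which chain diameter bounds the hard core:
#'   `"condensed"` (default, counterion-dressed) or `"bare"`.
#' @return An object of class `spherocylinder_shape`: list with `length`
#'   (axis length excluding caps, nm), `diameter` (nm), `total_length` (nm)
#'   and `area` (footprint, nm^2).
#' @export
#' @examples
#' molecule_shape(derive_size_parameters(parg_primitives(), n_monomers = 240))
molecule_shape <- function(derived, diameter = c("condensed", "bare")) {
  diameter <- match.arg(diameter)
  p <- attr(derived, "primitives")
  d <- if (diameter == "condensed") p$condensed_diameter else p$bare_diameter
  spherocylinder_shape(total_length = derived$contour_length_nm, diameter = d)
}

#' @rdname molecule_shape
#' @param total_length Tip-to-tip length (nm), at least `diameter`.
#' @export
spherocylinder_shape <- function(total_length, diameter) {
  if (diameter <= 0 || total_length < diameter) {
    stop("need total_length >= diameter > 0")
  }
  structure(list(length = total_length - diameter, diameter = diameter,
                 total_length = total_length,
                 area = footprint_area(total_length, diameter)),
            class = "spherocylinder_shape")
}

#' Export derived molecular geometry as JSON
#'
#' @param derived A `molecule_derived` object.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_molecule_json <- function(derived, path) {
  jsonlite::write_json(as.list(derived), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
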