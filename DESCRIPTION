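Package: rsaqcm
Title: Random Sequential Adsorption and QCM-D Inversion for Macroion
    Adsorption at Solid/Liquid Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative modelling of polyelectrolyte (macroion) adsorption
    on charged substrates such as silica. Derives molecular geometry
    (equivalent cylinder, aspect ratio, side-on footprint) from
    molecular-dynamics chain primitives, computes electrokinetic
    characteristics (zeta potential from streaming current, hydrodynamic
    diameter, effective charge from mobility and diffusivity), simulates
    random sequential adsorption of spherocylinders on a periodic plane with
    an electrostatic equivalent-hard-particle enlargement and scaled-particle
    -theory blocking functions, integrates convective-diffusion adsorption
    kinetics, and inverts quartz crystal microbalance frequency shifts to dry
    coverage under Sauerbrey, stiff-contact and lubricated soft-contact
    hydrodynamic models. Includes a synthetic-experiment generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
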