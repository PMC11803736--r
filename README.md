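# rsaqcm

Quantitative modelling of polyelectrolyte (macroion) adsorption on charged
substrates, built around a reference system: a 42 kg/mol linear
polyelectrolyte adsorbing side-on onto silica from 100 mM NaCl. The package
covers the full chain from molecular primitives to measurable signals:

1. **Molecular geometry** — equivalent cylinder, aspect ratio, side-on
   footprint and chain metrics derived from molecular-dynamics primitives
   (`derive_size_parameters()`, `footprint_area()`, `molecule_shape()`).
2. **Electrokinetics** — zeta potential from streaming current
   (Helmholtz–Smoluchowski), hydrodynamic diameter (Stokes–Einstein),
   effective charge from mobility and diffusivity (Lorentz–Stokes), Debye
   length (`zeta_from_streaming()`, `stokes_einstein_diameter()`,
   `electrokinetic_charge()`, `debye_length()`).
3. **Random sequential adsorption** — a compiled RSA kernel for 2D
   spherocylinders on a periodic box with exact segment–segment overlap
   tests, cell lists, jamming extrapolation, ghost-insertion measurement of
   the available-surface (blocking) function, and an electrostatic
   equivalent-hard-particle enlargement (`run_rsa()`, `rsa_jamming()`,
   `spt_blocking_function()`, `effective_dimensions()`).
4. **Adsorption kinetics** — flux-matching reduction of a hybrid
   convective-diffusion / surface-boundary-layer model with blocking-limited
   attachment and a rinse phase (`transport_params()`,
   `simulate_kinetics()`).
5. **QCM-D inversion** — Sauerbrey, stiff-contact and lubricated
   soft-contact conversions between per-overtone frequency shifts and dry
   coverage, plus the exact forward models (`qcm_params()`, `invert_qcm()`,
   `forward_frequency_shift()`).
6. **Synthetic experiments** — noisy per-overtone QCM or reflectometry
   traces with stored ground truth for end-to-end validation
   (`experiment_scenario()`, `synthesize_experiment()`).

Results come back as tibbles; result objects support `tidy()`, `glance()`
and `autoplot()`.

## Quick start

```r
library(rsaqcm)

# Geometry of the reference molecule (42 kg/mol, 240 monomers)
der <- derive_size_parameters(parg_primitives(), n_monomers = 240)
der$aspect_ratio            # ~35
der$footprint_condensed_nm2 # ~67 nm^2

# RSA jamming coverage at the pH 10.2 electrostatic conditions
shape <- molecule_shape(der)
zeta  <- parameter_set_for_ph(10.2)$zeta_V
eff   <- effective_dimensions(shape, zeta)
jam   <- rsa_jamming(shape, seeds = 1:3, effective = eff$shape,
                     max_attempts = 5e7)
jam$mean

# Kinetics and a synthetic QCM experiment
sc <- experiment_scenario(pH = 5.7, technique = "qcm")
ex <- synthesize_experiment(sc, theta_max = 0.37)
autoplot(ex$truth)

# Invert the noisy signal back to coverage with the soft-contact model
inv <- invert_qcm(ex$signal, model = "soft")
```

## Reference-value reproduction

`reproduce_tables()` recomputes every derived characterisation quantity of
the reference system (geometry, electrokinetic charges and diameters, QCM
constants, mass-coverage conversions) and compares it with the recorded
reference value:

```r
rt <- reproduce_tables()
all(rt$pass)
```

## Command-line interface

A thin wrapper lives at `inst/cli/rsaqcm.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","rsaqcm.R",package="rsaqcm"))')" \
    derive --out derived.json
```

Subcommands: `derive`, `rsa`, `kinetics`, `qcm-invert`, `synth`,
`reproduce-tables`. Options are read from a flat `key = value` config file
(`--config`), with `--seed`, `--model`, `--in`, `--out` flags; logs go to
stderr, data to files.

## Scripts

- `scripts/calibrate_rsa.R` — one-time calibration of the blocking-function
  coefficients and the electrostatic contact-energy prefactor frozen in
  `R/rsa.R`; writes `scripts/calibration_results.json`.
- `scripts/acceptance.R` — computes the headline results (footprint areas
  and the pH 10.2 jamming coverage) and writes them as JSON:
  `Rscript scripts/acceptance.R --seed 1 --out acceptance.json`.

## Tests

```r
testthat::test_dir("tests/testthat")
```

The suite includes fast unit and property tests plus slower stochastic
acceptance checks (disk jamming limit, blocking-function agreement,
jamming coverage under electrostatic enlargement) that take a few minutes.
See `vignettes/adsorption-models.Rmd` for the model descriptions, parameter
defaults, calibration account and known discrepancies.
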