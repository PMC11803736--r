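test_that("derived geometry matches hand-computed values", {
  der <- ref_derived()
  p <- parg_primitives()
  v_expected <- 1e27 * 42 / (1500 * physical_constants()$N_Av)
  expect_equal(der$volume_nm3, v_expected)
  expect_equal(der$sphere_diameter_nm, (6 * v_expected / pi)^(1 / 3))
  expect_equal(der$contour_length_nm, 240 * 0.20)
  expect_equal(der$cylinder_length_nm, 4 * v_expected / (pi * 1.1^2))
  expect_equal(der$aspect_ratio, der$cylinder_length_nm / 1.4)
  expect_equal(der$ete_nm, 9.88 * 240 / 50)
  expect_equal(der$rg_nm, 3.50 * 240 / 50)
  expect_identical(attr(der, "primitives"), p)
})

test_that("monomer count defaults to the exact mass ratio", {
  der <- derive_size_parameters(parg_primitives())
  expect_equal(der$n_monomers, 42 / 0.174)
  expect_equal(der$contour_length_nm, 42 / 0.174 * 0.20)
})

test_that("footprint area is rectangle plus caps and degenerates to a disk", {
  expect_equal(footprint_area(48, 1.1), (48 - 1.1) * 1.1 + pi * 1.1^2 / 4)
  expect_equal(footprint_area(2, 2), pi * 2^2 / 4)  # zero-length rod = disk
  expect_error(footprint_area(1, 2), "contour_length")
  expect_error(footprint_area(1, 0), "diameter")
})

test_that("chain metrics scale linearly with monomer count", {
  expect_equal(scale_chain_metric(9.88, 50, 50), 9.88)
  expect_equal(scale_chain_metric(10, 50, 100), 20)
  expect_equal(scale_chain_metric(c(9.88, 3.5), 50, 240),
               c(9.88, 3.5) * 4.8)
})

test_that("primitive validation rejects inconsistent inputs", {
  expect_error(molecule_primitives(42, 0.174, 1500, 0.2, 1.4, 1.1),
               "condensed_diameter")
  expect_error(molecule_primitives(0.1, 0.174, 1500, 0.2, 1.1, 1.4),
               "molar_mass")
  expect_error(molecule_primitives(42, 0.174, -1, 0.2, 1.1, 1.4),
               "positive")
})

test_that("molecule_shape uses the requested diameter", {
  cond <- ref_shape("condensed")
  bare <- ref_shape("bare")
  expect_s3_class(cond, "spherocylinder_shape")
  expect_equal(cond$diameter, 1.4)
  expect_equal(bare$diameter, 1.1)
  expect_equal(cond$total_length, 48)
  expect_equal(cond$length, 48 - 1.4)
  expect_equal(cond$area, footprint_area(48, 1.4))
})

test_that("spherocylinder_shape validates dimensions", {
  expect_error(spherocylinder_shape(1, 2), "total_length")
  expect_error(spherocylinder_shape(1, 0), "total_length")
  s <- spherocylinder_shape(3, 3)
  expect_equal(s$length, 0)
})

test_that("molecule JSON round trips", {
  der <- ref_derived()
  path <- withr::local_tempfile(fileext = ".json")
  write_molecule_json(der, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$volume_nm3, der$volume_nm3)
  expect_equal(back$aspect_ratio, der$aspect_ratio)
})
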