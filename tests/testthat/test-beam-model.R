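sharp_preset <- function(energy = "10FFF", sigma = 0.3) {
  p <- beam_preset(energy)
  p$sigma_penumbra <- sigma
  p
}

test_that("fVC field construction and leaf-shift perturbations", {
  f <- fvc_field()
  expect_equal(f$x2 - f$x1, 5)
  expect_equal(f$y2 - f$y1, 5)
  expect_equal(c(f$jaw_x, f$jaw_y), c(7.5, 7.5))
  expect_equal(fvc_field(1)$x2 - fvc_field(1)$x1, 7)
  expect_equal(fvc_field(-1)$x2 - fvc_field(-1)$x1, 3)
  expect_error(fvc_field(3), "leaf_shift")
})

test_that("fluence has the stated structure at the aperture and shielded regions", {
  p <- sharp_preset()
  f <- fvc_field()
  expect_gte(fluence(f, p, 0, 0), 0.99)
  expect_equal(fluence(f, p, 0, 30), p$jaw_transmission)
  expect_equal(fluence(f, p, 30, 0), p$jaw_transmission)
  # effective-edge midpoint sits at (1 + mlc_transmission) / 2
  expect_equal(fluence(f, p, 2.5 + p$leaf_end_offset, 0),
               (1 + p$mlc_transmission) / 2, tolerance = 1e-3)
  # symmetry under x -> -x for the unshifted field
  x <- seq(-6, 6, by = 0.1)
  expect_equal(fluence(f, p, x, 0), rev(fluence(f, p, -x, 0)), tolerance = 1e-12)
  # bounded by the transmissions
  xy <- expand.grid(x = seq(-20, 20, 0.5), y = seq(-20, 20, 0.5))
  fl <- fluence(f, p, xy$x, xy$y)
  expect_true(all(fl >= p$jaw_transmission - 1e-12 & fl <= 1 + 1e-12))
})

test_that("fluence X profile FWHM equals the effective aperture width", {
  # at small penumbra sigma the erf edges do not overlap and the FWHM is the
  # geometric width plus twice the rounded-leaf offset
  for (e in c("6FFF", "10FFF")) {
    p <- sharp_preset(e)
    x <- seq(-8, 8, by = 0.005)
    w <- fwhm(x, fluence(fvc_field(), p, x, 0))
    expect_equal(w, 5 + 2 * p$leaf_end_offset, tolerance = 0.05)
    # X (leaf-end) profile is wider than Y (leaf-side) at the 50% level
    wy <- fwhm(x, fluence(fvc_field(), p, 0, x))
    expect_gt(w, wy)
  }
  # at clinical sigma the overlapping edges only widen the profile further
  p10 <- beam_preset("10FFF")
  x <- seq(-8, 8, by = 0.005)
  expect_gte(fwhm(x, fluence(fvc_field(), p10, x, 0)), 5 + 2 * p10$leaf_end_offset)
})

test_that("output factors reproduce the calibration anchors", {
  f <- fvc_field()
  expect_equal(field_output_factor(f, beam_preset("10FFF"), "95/5"), 0.550, tolerance = 1e-6)
  expect_equal(field_output_factor(f, beam_preset("6FFF"), "95/5"), 0.605, tolerance = 1e-6)
  expect_equal(field_output_factor(f, beam_preset("10FFF"), "90/10"), 0.510, tolerance = 1e-6)
  expect_equal(field_output_factor(f, beam_preset("6FFF"), "90/10"), 0.560, tolerance = 1e-6)
})

test_that("output factor is strictly monotone in leaf shift and normalized at reference", {
  p <- beam_preset("10FFF")
  shifts <- seq(-1, 1, by = 0.25)
  ofs <- vapply(shifts, function(s) field_output_factor(fvc_field(s), p), numeric(1))
  expect_true(all(diff(ofs) > 0))
  # a reference-size aperture interpolates to unity
  expect_equal(p$of_funs[["95/5"]](100), 1.0, tolerance = 1e-9)
})

test_that("TMR tables peak near d_max and decrease beyond it", {
  for (e in c("6FFF", "10FFF")) {
    p <- beam_preset(e)
    d <- seq(30, 250, by = 1)
    expect_true(all(diff(tmr(p, d)) < 0))
    expect_lt(tmr(p, 100) / tmr(p, 50), 1)
  }
})

test_that("preset validation rejects malformed tables", {
  raw <- yaml::read_yaml(system.file("extdata", "preset_10fff.yaml", package = "fvcdose"))
  bad <- raw
  bad$of_tables$`95/5`$value <- rev(bad$of_tables$`95/5`$value)
  expect_error(fvcdose:::validate_beam_preset(bad), "increasing")
  bad2 <- raw
  bad2$mlc_transmission <- 0.2
  expect_error(fvcdose:::validate_beam_preset(bad2), "0.05")
})
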