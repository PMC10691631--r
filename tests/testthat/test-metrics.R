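test_that("FWHM handles top hats, Gaussians and blurred edges", {
  x <- seq(-10, 10, by = 0.01)
  expect_equal(fwhm(x, as.numeric(abs(x) <= 2.5)), 5.0, tolerance = 0.011)
  expect_equal(fwhm(x, exp(-x^2 / (2 * 2^2))), 2 * sqrt(2 * log(2)) * 2,
               tolerance = 0.02)
  # error-function-blurred 5 mm top hat keeps its width while the edges are
  # well separated (sigma up to ~1 mm)
  for (s in c(0.3, 0.6, 1.0)) {
    prof <- pnorm((2.5 - x) / s) - pnorm((-2.5 - x) / s)
    expect_equal(fwhm(x, prof), 5.0, tolerance = 0.05)
  }
  expect_error(fwhm(x, exp(x)), "half maximum")
})

test_that("s_clin is the geometric mean of the two profile FWHMs", {
  expect_equal(s_clin(top_hat_plane(6, 6)), 6.0, tolerance = 0.05)
  expect_equal(s_clin(top_hat_plane(5.7, 6.0)), sqrt(5.7 * 6.0), tolerance = 0.05)
  expect_equal(sqrt(5.7 * 6.0), 5.85, tolerance = 0.005)
})

test_that("single-field S_clin lands in the clinical ranges for both beams", {
  s6 <- s_clin(single_field_plane(beam_preset("6FFF")))
  s10 <- s_clin(single_field_plane(beam_preset("10FFF")))
  expect_gte(s6, 5.7); expect_lte(s6, 6.0)
  expect_gte(s10, 6.0); expect_lte(s10, 6.4)
})

test_that("isodose geometry recovers circles and ellipses", {
  # circular spot whose 50% contour has radius 2.5 mm
  circ <- ellipse_plane(5, 5, 0.5)
  ig <- isodose_geometry(circ, 0.5)
  expect_equal(ig$d_major, 5.0, tolerance = 0.1)
  expect_equal(ig$d_minor, 5.0, tolerance = 0.1)
  # printed 50% axes: 7.0 x 5.7 mm
  ig2 <- isodose_geometry(ellipse_plane(7.0, 5.7, 0.5), 0.5)
  expect_equal(ig2$d_major, 7.0, tolerance = 0.05)
  expect_equal(ig2$d_minor, 5.7, tolerance = 0.05)
  expect_equal(ig2$d_equiv, 6.32, tolerance = 0.05)
  # printed 90% axes: 2.1 x 1.82 mm
  ig3 <- isodose_geometry(ellipse_plane(2.1, 1.82, 0.9, step = 0.01), 0.9)
  expect_equal(ig3$d_equiv, 1.96, tolerance = 0.02)
  expect_equal(ig3$d_equiv, sqrt(ig3$d_major * ig3$d_minor), tolerance = 1e-9)
})

test_that("isodose diameters are scale-equivariant and fail on open contours", {
  pl <- ellipse_plane(6, 4, 0.5)
  ig <- isodose_geometry(pl, 0.5)
  k <- 2.5
  pl_k <- dose_plane(pl$values, pl$u * k, pl$v * k)
  ig_k <- isodose_geometry(pl_k, 0.5)
  expect_equal(ig_k$d_major, k * ig$d_major, tolerance = 1e-6)
  expect_equal(ig_k$d_minor, k * ig$d_minor, tolerance = 1e-6)
  # a contour wider than the map is open
  expect_error(isodose_geometry(ellipse_plane(6, 4, 0.5), 0.05), "open|contour")
})

test_that("percent difference uses the symmetric convention and matches the printed table", {
  calc <- c(0.605, 0.558, 0.560, 0.510, 0.424)
  meas <- c(0.620, 0.577, 0.568, 0.515, 0.435)
  expect_equal(round(percent_difference(calc, meas), 2),
               c(2.45, 3.35, 1.42, 0.98, 2.56))
  expect_equal(percent_difference(0.5, 0.5), 0)
  expect_equal(percent_difference(0.4, 0.5), -percent_difference(0.5, 0.4))
  expect_error(percent_difference(-1, 2), "positive")
})

test_that("organ-at-risk maximum dose behaves with distance from the target", {
  dose <- cached_default_dose()
  inside <- oar_max_dose(dose, c(0, 0, 0), 10)
  expect_equal(inside$max_dose, max(dose$values))
  far <- oar_max_dose(dose, c(0, 35, 25), 5)
  expect_lt(far$max_dose, 0.05 * max(dose$values))
  gaps <- seq(3, 8, by = 1)
  mx <- vapply(gaps, function(g) {
    oar_max_dose(dose, c(0, 0, -(10 + g)), 10)$max_dose
  }, numeric(1))
  expect_true(all(diff(mx) < 0))
  expect_error(oar_max_dose(dose, c(500, 0, 0), 5), "intersect")
})

test_that("leaf-shift study shows the expected sensitivity orderings", {
  st <- leaf_shift_study()
  ref <- dplyr::filter(st, shift == 0)
  expect_true(all(abs(ref$of_pct_change) < 1e-12))
  expect_true(all(abs(ref$dose_pct_change) < 1e-12))
  wide <- dplyr::filter(st, shift != 0)
  for (en in c("6FFF", "10FFF")) {
    for (se in c("95/5", "90/10")) {
      sub <- dplyr::filter(wide, energy == en, setting == se)
      for (col in c("of_pct_change", "dose_pct_change")) {
        expect_gt(abs(sub[[col]][sub$shift == -1]), abs(sub[[col]][sub$shift == -0.5]))
        expect_gt(abs(sub[[col]][sub$shift == 1]), abs(sub[[col]][sub$shift == 0.5]))
      }
    }
  }
  # the 10 MV FFF beam is the more stable one at every shift and setting
  cmp <- dplyr::inner_join(
    dplyr::filter(wide, energy == "6FFF"),
    dplyr::filter(wide, energy == "10FFF"),
    by = c("setting", "shift"), suffix = c("_6", "_10")
  )
  expect_true(all(abs(cmp$of_pct_change_10) < abs(cmp$of_pct_change_6)))
  expect_true(all(abs(cmp$dose_pct_change_10) < abs(cmp$dose_pct_change_6)))
})
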