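test_that("point dose reproduces the calibration dose/MU at both clinical settings", {
  f <- fvc_field()
  g0 <- beam_geometry(0, 0, 0)
  iso <- c(0, 0, 0)
  expect_equal(point_dose(g0, 1, f, beam_preset("10FFF"), iso, phantom("slab", 50)),
               0.547, tolerance = 1e-3)
  expect_equal(point_dose(g0, 1, f, beam_preset("10FFF"), iso, phantom("slab", 100)),
               0.432, tolerance = 1e-3)
  expect_equal(point_dose(g0, 1, f, beam_preset("6FFF"), iso, phantom("slab", 50)),
               0.558, tolerance = 1e-3)
  expect_equal(point_dose(g0, 1, f, beam_preset("6FFF"), iso, phantom("slab", 100)),
               0.424, tolerance = 1e-3)
})

test_that("dose is linear in MU and additive over control points", {
  f <- fvc_field()
  p <- beam_preset("10FFF")
  phan <- phantom("sphere", 80)
  g <- beam_geometry(40, 10, 20)
  pts <- rbind(c(0, 0, 0), c(2, 1, -1), c(-3, 4, 2))
  expect_equal(point_dose(g, 2, f, p, pts, phan),
               2 * point_dose(g, 1, f, p, pts, phan), tolerance = 1e-12)
  # superposition: a plan split into two halves sums to the whole
  plan <- default_tgn_plan(12, seed = 2)
  cps <- plan_control_points(plan, 5, total_mu = 1000)
  d_all <- fvcdose:::dose_at_points(cps, f, p, pts, phan)
  d_a <- fvcdose:::dose_at_points(cps[cps$arc <= 6, ], f, p, pts, phan)
  d_b <- fvcdose:::dose_at_points(cps[cps$arc > 6, ], f, p, pts, phan)
  expect_equal(d_a + d_b, d_all, tolerance = 1e-12)
})

test_that("halving the gantry spacing changes voxel doses by less than 1 percent", {
  plan <- default_tgn_plan(12, seed = 1)
  f <- fvc_field()
  p <- beam_preset("10FFF")
  phan <- phantom("sphere", 80)
  pts <- as.matrix(expand.grid(x = seq(-5, 5, 2), y = seq(-5, 5, 2),
                               z = seq(-5, 5, 2), KEEP.OUT.ATTRS = FALSE))
  d2 <- fvcdose:::dose_at_points(plan_control_points(plan, 2, total_mu = 1000), f, p, pts, phan)
  d1 <- fvcdose:::dose_at_points(plan_control_points(plan, 1, total_mu = 1000), f, p, pts, phan)
  expect_lt(max(abs(d1 - d2)) / max(d1), 0.01)
})

test_that("a uniformly weighted full arc gives a rotationally symmetric dose", {
  # uniform MU per degree; dose sampled on a 2 mm circle around the gantry
  # rotation axis through the isocenter
  cps <- sine_weights(one_arc(0, 0), 2, mu = 1000)
  cps$mu <- sum(cps$mu) / nrow(cps)
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  circle <- cbind(2 * cos(th), 0, 2 * sin(th))
  d <- fvcdose:::dose_at_points(cps, fvc_field(), beam_preset("10FFF"),
                                circle, phantom("sphere", 80))
  expect_lt(stats::sd(d) / mean(d), 0.01)
})

test_that("compute_dose normalizes the maximum voxel to the prescription", {
  plan <- default_tgn_plan(10, seed = 4)
  dose <- compute_dose(plan, phantom("sphere", 80),
                       grid_spec(c(-6, 6), c(-6, 6), c(-6, 6), spacing = 2))
  expect_equal(max(dose$values), plan$prescription)
  expect_true(all(dose$values >= 0) && all(is.finite(dose$values)))
})

test_that("plane extraction preserves symmetry, maxima and interpolation order", {
  dose <- cached_default_dose()
  pl <- extract_plane(dose, "coronal", 0)
  expect_equal(max(pl$values), max(dose$values[, , which(dose$z == 0)]), tolerance = 1e-12)
  # planes bracketing the isocenter interpolate monotonically on a smooth dose
  p_lo <- extract_plane(dose, "coronal", -0.5)
  p_hi <- extract_plane(dose, "coronal", 0.5)
  i <- which(dose$x == 0)
  mid <- extract_plane(dose, "coronal", 0)$values[i, i]
  expect_true(min(p_lo$values[i, i], p_hi$values[i, i]) <= mid + 1e-9)
  expect_error(extract_plane(dose, "coronal", 99), "outside")
  # a symmetric synthetic grid yields a flip-symmetric plane
  u <- seq(-5, 5)
  blob <- exp(-outer(outer(u^2, u^2, `+`), u^2, `+`) / 20)
  gsym <- structure(list(values = blob, x = u, y = u, z = u, spacing = 1,
                         total_mu = 1, plan = NULL), class = "dose_grid")
  ps <- extract_plane(gsym, "coronal", 0)
  expect_equal(ps$values, ps$values[rev(seq_along(u)), ], tolerance = 1e-6)
})
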