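test_that("plan construction validates arcs and normalizes weights", {
  arcs <- dplyr::bind_rows(one_arc(30, 90), one_arc(350, 310, "CCW"))
  arcs$weight <- c(3, 1)
  plan <- fvc_plan(arcs)
  expect_equal(sum(plan$arcs$weight), 1)
  expect_equal(plan$arcs$weight, c(0.75, 0.25))
  expect_error(fvc_plan(one_arc(0, 0.5)), "span")
  expect_error(fvc_plan(dplyr::mutate(one_arc(30, 90), weight = 0)), "weight")
})

test_that("sine weighting integrates |sin| exactly over gantry bins", {
  # symmetric arc about gantry 90: mirrored control points get equal MU
  cp <- sine_weights(one_arc(60, 120), delta_gantry = 2, mu = 10)
  expect_equal(cp$mu, rev(cp$mu), tolerance = 1e-12)
  expect_equal(which.max(cp$mu), nrow(cp) %/% 2 + c(0, 1)[1 + nrow(cp) %% 2])
  # exact MU conservation for awkward spans and spacings
  for (sp in list(c(17, 163), c(350, 40), c(200, 250))) {
    for (dg in c(0.7, 2, 10)) {
      cp <- sine_weights(one_arc(sp[1], sp[2]), dg, mu = 123.4)
      expect_equal(sum(cp$mu), 123.4, tolerance = 1e-12)
    }
  }
  # dose per degree ratio between bins centered on 90 and 30 degrees is
  # sin(90)/sin(30) = 2, exactly, under per-bin integration
  w90 <- sine_weights(one_arc(89.5, 90.5), 1, mu = 1)
  w30 <- sine_weights(one_arc(29.5, 30.5), 1, mu = 1)
  a90 <- fvcdose:::abs_sin_integral(90.5) - fvcdose:::abs_sin_integral(89.5)
  a30 <- fvcdose:::abs_sin_integral(30.5) - fvcdose:::abs_sin_integral(29.5)
  expect_equal(a90 / a30, 2, tolerance = 1e-9)
  expect_equal(nrow(w90), 1)
  # weighting is invariant under arc reversal
  fw <- sine_weights(one_arc(40, 140, "CW"), 2, mu = 5)
  bw <- sine_weights(one_arc(140, 40, "CCW"), 2, mu = 5)
  expect_equal(fw$mu, rev(bw$mu), tolerance = 1e-12)
})

test_that("plan discretization conserves total MU for any spacing", {
  plan <- default_tgn_plan(12, seed = 3)
  for (dg in c(1, 2, 5)) {
    cps <- plan_control_points(plan, dg, total_mu = 5000)
    expect_equal(sum(cps$mu), 5000, tolerance = 1e-9)
  }
})

test_that("default TGN plan respects its geometric constraints", {
  plan <- default_tgn_plan(12, seed = 1)
  td <- tidy(plan)
  expect_equal(nrow(td), 12)
  expect_true(all(td$span >= 30 & td$span <= 90))
  expect_true(all(td$collimator >= 0 & td$collimator <= 90))
  expect_true(all(td$couch >= -90 & td$couch <= 90))
  expect_equal(anyDuplicated(td$couch), 0)
  # deterministic in the seed
  expect_identical(tidy(default_tgn_plan(12, seed = 5)),
                   tidy(default_tgn_plan(12, seed = 5)))
  expect_error(default_tgn_plan(9), "n_arcs")
  expect_error(default_tgn_plan(15), "n_arcs")
})

test_that("no two control-point beam directions nearly coincide", {
  plan <- default_tgn_plan(12, seed = 1)
  d <- fvcdose:::cp_directions(plan_control_points(plan, 2))
  cosang <- tcrossprod(d)
  diag(cosang) <- -1
  min_sep <- acos(pmin(pmax(max(cosang), -1), 1)) * 180 / pi
  expect_gt(min_sep, 0.5)
})

test_that("direction density is uniform in the many-arc full-sphere limit", {
  arcs <- tibble::tibble(couch = seq(-90, 90, length.out = 73)[-73],
                         collimator = 0, gantry_start = 0, gantry_stop = 0,
                         direction = "CW", weight = 1)
  cps <- purrr::list_rbind(purrr::imap(
    split(arcs, seq_len(nrow(arcs))),
    function(a, i) dplyr::mutate(sine_weights(a, 2, mu = 1), arc = as.integer(i))
  ))
  dd <- direction_density(cps, n_bins = 60)
  expect_lt(dd$cv, 0.10)
  expect_equal(dd$n_bins_covered, 64)
})

test_that("direction density degenerates correctly and favours sine weighting", {
  # single static beam: all MU in one bin of the covered hemisphere
  one <- tibble::tibble(gantry = 45, couch = 0, collimator = 0, mu = 1, arc = 1L)
  dd1 <- direction_density(one, n_bins = 60)
  expect_equal(dd1$cv, sqrt(dd1$n_bins_covered), tolerance = 0.01)
  # sine weighting spreads the default plan more evenly than flat weighting
  plan <- default_tgn_plan(12, seed = 1)
  cps <- plan_control_points(plan, 2)
  flat <- dplyr::ungroup(dplyr::mutate(dplyr::group_by(cps, arc),
                                       mu = sum(mu) / dplyr::n()))
  expect_lt(direction_density(cps, 60)$cv, direction_density(flat, 60)$cv)
})
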