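# shared fixtures; heavy objects are computed once per session and cached

.fvc_cache <- new.env(parent = emptyenv())

# default 12-arc 10FFF plan dose on a 1 mm grid covering the detector extent
cached_default_dose <- function() {
  if (is.null(.fvc_cache$dose)) {
    plan <- default_tgn_plan(12, energy = "10FFF", prescription = 7500, seed = 1)
    .fvc_cache$dose <- compute_dose(
      plan, phantom("sphere", 80),
      grid_spec(c(-40, 40), c(-40, 40), c(-30, 30), spacing = 1)
    )
  }
  .fvc_cache$dose
}

cached_coronal_plane <- function() {
  if (is.null(.fvc_cache$coronal)) {
    .fvc_cache$coronal <- extract_plane(cached_default_dose(), "coronal", 0)
  }
  .fvc_cache$coronal
}

# planar dose of a single static nominal field at the 95/5 reference setting
single_field_plane <- function(preset, step = 0.05, half = 8) {
  u <- seq(-half, half, by = step)
  pts <- as.matrix(expand.grid(x = u, y = u, z = 0, KEEP.OUT.ATTRS = FALSE))
  cps <- tibble::tibble(gantry = 0, couch = 0, collimator = 0, mu = 1, arc = 1L)
  vals <- fvcdose:::dose_at_points(cps, fvc_field(), preset, pts, phantom("slab", 50))
  dose_plane(matrix(vals, nrow = length(u)), u, u)
}

# smooth seeded random planar map pair: sum of Gaussian bumps, the evaluated
# copy rigidly shifted by < 0.5 mm, rescaled within 3 percent and given 1
# percent multiplicative noise -- the regime of a realistic planar QA pair
random_map_pair <- function(seed, n = 21) {
  withr::with_seed(seed, {
    u <- seq(-(n - 1) / 2, (n - 1) / 2, by = 1)
    g <- expand.grid(u = u, v = u, KEEP.OUT.ATTRS = FALSE)
    nb <- 3
    cx <- stats::runif(nb, -5, 5); cy <- stats::runif(nb, -5, 5)
    sg <- stats::runif(nb, 2, 5); am <- stats::runif(nb, 50, 100)
    bumps <- function(du, dv) {
      out <- 0
      for (i in seq_len(nb)) {
        out <- out + am[i] *
          exp(-((g$u - du - cx[i])^2 + (g$v - dv - cy[i])^2) / (2 * sg[i]^2))
      }
      out
    }
    ref <- bumps(0, 0)
    ev <- bumps(stats::runif(1, -0.5, 0.5), stats::runif(1, -0.5, 0.5)) *
      (1 + stats::rnorm(n^2, 0, 0.01)) * stats::runif(1, 0.97, 1.03)
    list(ref = dose_plane(matrix(ref, n), u, u),
         ev = dose_plane(matrix(ev, n), u, u))
  })
}

# separable top-hat planar map with exact FWHMs (sharp edges)
top_hat_plane <- function(width_x, width_y, step = 0.05, half = 8) {
  u <- seq(-half, half, by = step)
  fx <- as.numeric(abs(u) <= width_x / 2)
  fy <- as.numeric(abs(u) <= width_y / 2)
  dose_plane(outer(fx, fy) * 100, u, u)
}

# elliptical dose spot whose level contour has the requested axis diameters
ellipse_plane <- function(d_major, d_minor, level, step = 0.02) {
  half <- max(d_major, d_minor)
  u <- seq(-half, half, by = step)
  g <- expand.grid(u = u, v = u, KEEP.OUT.ATTRS = FALSE)
  r2 <- (g$u / (d_major / 2))^2 + (g$v / (d_minor / 2))^2
  # radially Gaussian spot: value = level exactly on the requested ellipse
  vals <- exp(log(level) * r2)
  dose_plane(matrix(vals, length(u)), u, u)
}

one_arc <- function(start, stop, direction = "CW", couch = 0, collimator = 0) {
  tibble::tibble(couch = couch, collimator = collimator, gantry_start = start,
                 gantry_stop = stop, direction = direction, weight = 1)
}

cached_qa_session <- function() {
  if (is.null(.fvc_cache$session)) {
    dose <- cached_default_dose()
    .fvc_cache$session <- simulate_qa_session(dose$plan, phantom("sphere", 80),
                                              dose = dose)
  }
  .fvc_cache$session
}
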