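#' Synthetic diode-array specification
#'
#' Parameters of the synthetic planar measurement emulating a
#' stereotactic-QA diode array: 2.47 mm detector pitch over a 77 mm x 77 mm
#' square lattice, multiplicative Gaussian noise, an optional sub-mm
#' registration offset of the array, and a small extra Gaussian blur
#' (`widening_sigma`) modelling the systematic widening of measured profiles
#' relative to the calculated ones.
#'
#' @param pitch Detector spacing in mm.
#' @param extent Length-2 array extent in mm.
#' @param noise_sd Relative (multiplicative) noise standard deviation, in
#'   `[0, 0.1]`.
#' @param registration_offset Length-2 array registration offset in mm.
#' @param widening_sigma Extra blur in mm applied before sampling.
#' @param seed Integer seed making the noise reproducible.
#' @return A `detector_spec` object.
#' @export
detector_spec <- function(pitch = 2.47, extent = c(77, 77), noise_sd = 0.01,
                          registration_offset = c(0, 0), widening_sigma = 0.3,
                          seed = 1) {
  stopifnot(pitch > 0, length(extent) == 2, all(extent > 0),
            noise_sd >= 0, noise_sd <= 0.1, length(registration_offset) == 2,
            widening_sigma >= 0)
  structure(
    list(pitch = pitch, extent = extent, noise_sd = noise_sd,
         registration_offset = registration_offset,
         widening_sigma = widening_sigma, seed = seed),
    class = "detector_spec"
  )
}

# separable Gaussian blur of a dose_plane (integrated-kernel weights,
# edge-renormalized)
blur_plane <- function(plane, sigma) {
  if (sigma <= 0) return(plane)
  h <- plane$u[2] - plane$u[1]
  r <- max(1L, ceiling(4 * sigma / h))
  edges <- (seq(-r, r + 1) - 0.5) * h
  k <- diff(stats::pnorm(edges, sd = sigma))
  k <- k / sum(k)
  conv1 <- function(m) {
    # convolve columns of m with k, renormalizing at the edges
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wt <- rep(0, n)
    for (i in seq_along(k)) {
      off <- i - r - 1L
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + k[i] * m[src[ok], ]
      wt[ok] <- wt[ok] + k[i]
    }
    out / wt
  }
  vals <- conv1(plane$values)
  vals <- t(conv1(t(vals)))
  plane$values <- vals
  plane
}

# odd detector counts so one diode sits exactly on the beam axis, as in the
# physical array; the lattice then spans the largest odd multiple of the
# pitch that fits the extent
detector_lattice <- function(spec) {
  n_u <- 2 * floor(spec$extent[1] / (2 * spec$pitch)) + 1
  n_v <- 2 * floor(spec$extent[2] / (2 * spec$pitch)) + 1
  list(u = (seq_len(n_u) - (n_u + 1) / 2) * spec$pitch,
       v = (seq_len(n_v) - (n_v + 1) / 2) * spec$pitch)
}

#' Synthesize a diode-array measurement of a planar dose
#'
#' Blurs the calculated planar dose with the spec's widening sigma, shifts
#' the sampling positions by the registration offset, resamples at the
#' detector lattice (bilinear), and applies multiplicative Gaussian noise.
#' Deterministic for a fixed seed.
#'
#' @param plane Calculated `dose_plane`; must cover the detector extent.
#' @param spec A [detector_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return A `dose_plane` on the detector lattice.
#' @export
sample_measurement <- function(plane, spec = detector_spec(), seed = NULL) {
  stopifnot(inherits(plane, "dose_plane"), inherits(spec, "detector_spec"))
  lat <- detector_lattice(spec)
  need_u <- range(lat$u) + spec$registration_offset[1]
  need_v <- range(lat$v) + spec$registration_offset[2]
  if (need_u[1] < min(plane$u) || need_u[2] > max(plane$u) ||
      need_v[1] < min(plane$v) || need_v[2] > max(plane$v)) {
    stop("detector extent exceeds the calculated map coverage", call. = FALSE)
  }
  blurred <- blur_plane(plane, spec$widening_sigma)
  pts <- expand.grid(u = lat$u, v = lat$v, KEEP.OUT.ATTRS = FALSE)
  vals <- interp_plane(blurred,
                       pts$u + spec$registration_offset[1],
                       pts$v + spec$registration_offset[2])
  if (spec$noise_sd > 0) {
    vals <- withr::with_seed(if (is.null(seed)) spec$seed else seed, {
      vals * (1 + stats::rnorm(length(vals), 0, spec$noise_sd))
    })
  }
  out <- new_dose_plane(matrix(vals, nrow = length(lat$u)), lat$u, lat$v,
                        plane$axes, plane$orientation, plane$offset)
  attr(out, "detector_spec") <- spec
  out
}

#' Simulate a full patient-specific QA session
#'
#' Computes the cumulative coronal planar dose of a plan through the
#' isocenter plus the per-arc (field-by-field) planar doses, synthesizes a
#' diode-array measurement of each, and tabulates the per-arc central-axis
#' dose-per-MU comparison -- everything needed for the gamma and dose-output
#' QA of an arc plan, with no hardware.
#'
#' @param plan An [fvc_plan()].
#' @param phan A [phantom()] (default: 80 mm water sphere).
#' @param preset A [beam_preset()]; defaults to the plan's energy.
#' @param detector A [detector_spec()].
#' @param grid A [grid_spec()] covering the detector extent in the coronal
#'   plane.
#' @param delta_gantry Arc discretization in degrees.
#' @param dose Optional precomputed `dose_grid` for this plan (skips the 3D
#'   dose computation).
#' @return A `qa_session` list: `calculated` and `measured` cumulative
#'   planes, `fields` (per-arc list of calculated/measured pairs),
#'   `axis_table` (per-arc central-axis dose/MU comparison) and the scaled
#'   control points.
#' @export
simulate_qa_session <- function(plan, phan = phantom("sphere", 80), preset = NULL,
                                detector = detector_spec(),
                                grid = grid_spec(c(-40, 40), c(-40, 40), c(-30, 30)),
                                delta_gantry = 2, dose = NULL) {
  stopifnot(inherits(plan, "fvc_plan"))
  if (is.null(preset)) preset <- beam_preset(plan$energy)
  if (is.null(dose)) {
    dose <- compute_dose(plan, phan, grid, preset, delta_gantry)
  } else {
    stopifnot(inherits(dose, "dose_grid"))
    grid <- structure(dose[c("x", "y", "z", "spacing")], class = "grid_spec")
  }
  calculated <- extract_plane(dose, "coronal", 0)
  cps <- plan_control_points(plan, delta_gantry, total_mu = dose$total_mu)
  plane_pts <- as.matrix(expand.grid(x = grid$x, y = grid$y, z = 0,
                                     KEEP.OUT.ATTRS = FALSE))
  measured <- sample_measurement(calculated, detector, seed = detector$seed)
  fields <- purrr::map(split(cps, cps$arc), function(cp_arc) {
    vals <- dose_at_points(cp_arc, plan$field, preset, plane_pts, phan)
    calc <- new_dose_plane(matrix(vals, nrow = length(grid$x)), grid$x, grid$y,
                           calculated$axes, "coronal")
    meas <- sample_measurement(calc, detector,
                               seed = detector$seed + unique(cp_arc$arc))
    list(calculated = calc, measured = meas)
  })
  axis_table <- purrr::imap(fields, function(fl, arc_id) {
    mu_arc <- sum(cps$mu[cps$arc == as.integer(arc_id)])
    calc_axis <- interp_plane(fl$calculated, 0, 0)
    meas_axis <- interp_plane(fl$measured, 0, 0)
    tibble::tibble(
      arc = as.integer(arc_id), mu = mu_arc,
      calc_dose_per_mu = calc_axis / mu_arc,
      meas_dose_per_mu = meas_axis / mu_arc,
      pct_difference = percent_difference(calc_axis, meas_axis)
    )
  }) |> purrr::list_rbind()
  structure(
    list(calculated = calculated, measured = measured, fields = fields,
         axis_table = axis_table, dose = dose, plan = plan,
         detector = detector),
    class = "qa_session"
  )
}

#' @export
print.qa_session <- function(x, ...) {
  cat(sprintf("<qa_session> %d fields + cumulative plane (%s, %.0f cGy max)\n",
              length(x$fields), x$plan$energy, max(x$calculated$values)))
  invisible(x)
}

#' Gamma summary of a QA session
#'
#' Scores each field-by-field pair with the field criteria and the
#' cumulative pair with the cumulative criteria, mirroring clinical
#' patient-specific QA reporting.
#'
#' @param session A `qa_session` from [simulate_qa_session()].
#' @param field_criteria Criteria for the per-field comparisons (default
#'   3 percent / 1 mm, 10 percent threshold).
#' @param cumulative_criteria Criteria for the cumulative plane (default
#'   2 percent / 1 mm, 10 percent threshold).
#' @return A tibble with one row per field plus one `cumulative` row.
#' @export
qa_gamma_summary <- function(session,
                             field_criteria = gamma_criteria(3, 1, 10),
                             cumulative_criteria = gamma_criteria(2, 1, 10)) {
  stopifnot(inherits(session, "qa_session"))
  per_field <- purrr::imap(session$fields, function(fl, arc_id) {
    g <- gamma_map(fl$calculated, fl$measured, field_criteria)
    dplyr::mutate(glance.gamma_result(g), scope = paste0("field_", arc_id),
                  .before = 1)
  }) |> purrr::list_rbind()
  g_cum <- gamma_map(session$calculated, session$measured, cumulative_criteria)
  dplyr::bind_rows(
    per_field,
    dplyr::mutate(glance.gamma_result(g_cum), scope = "cumulative", .before = 1)
  )
}
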