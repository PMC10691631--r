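#' Full width at half maximum of a 1D profile
#'
#' Finds the two 50-percent-of-maximum crossings by linear interpolation and
#' returns their separation. The profile must fall below half maximum on both
#' sides of its peak.
#'
#' @param position Sample positions in mm (strictly increasing), or a data
#'   frame with columns `position` and `dose`.
#' @param dose Sampled dose values (omit when `position` is a data frame).
#' @return FWHM in mm.
#' @examples
#' x <- seq(-10, 10, by = 0.1)
#' fwhm(x, exp(-x^2 / (2 * 2^2)))  # 2*sqrt(2*log(2))*2 = 4.71
#' @export
fwhm <- function(position, dose = NULL) {
  if (is.null(dose)) {
    dose <- position$dose
    position <- position$position
  }
  stopifnot(length(position) == length(dose), length(position) >= 5,
            !is.unsorted(position, strictly = TRUE))
  half <- max(dose) / 2
  above <- dose >= half
  i1 <- which(above)[1]
  i2 <- max(which(above))
  if (i1 == 1 || i2 == length(dose)) {
    stop("profile does not fall below half maximum on both sides", call. = FALSE)
  }
  cross <- function(ia, ib) {
    position[ia] + (half - dose[ia]) * (position[ib] - position[ia]) / (dose[ib] - dose[ia])
  }
  cross(i2, i2 + 1) - cross(i1, i1 - 1)
}

# central-axis profiles of a planar map, bilinearly interpolated through (0, 0)
central_profiles <- function(plane) {
  list(
    x = tibble::tibble(position = plane$u, dose = interp_plane(plane, plane$u, rep(0, length(plane$u)))),
    y = tibble::tibble(position = plane$v, dose = interp_plane(plane, rep(0, length(plane$v)), plane$v))
  )
}

#' Equivalent square small-field size of a planar dose map
#'
#' The geometric mean of the in-plane (X) and cross-plane (Y) central-axis
#' profile FWHMs, `sqrt(FWHM_X * FWHM_Y)` -- the standard descriptor of a
#' small rectangular field's clinical size.
#'
#' @param plane A `dose_plane` peaked near the origin.
#' @return Equivalent square field size in mm.
#' @export
s_clin <- function(plane) {
  stopifnot(inherits(plane, "dose_plane"))
  pr <- central_profiles(plane)
  sqrt(fwhm(pr$x) * fwhm(pr$y))
}

#' Major/minor/equivalent diameters of an isodose contour
#'
#' Extracts the closed contour at `level` times the planar maximum
#' (marching squares with linear interpolation), measures its caliper width
#' in 72 directions (2.5 degree steps), and reports the maximal width as the
#' major diameter, the minimal width as the minor diameter, and their
#' geometric mean `sqrt(d_major * d_minor)` as the diameter of the equivalent
#' circle.
#'
#' @param plane A `dose_plane`.
#' @param level Isodose level as a fraction of the planar maximum, in (0, 1).
#' @return A one-row tibble: `level`, `d_major`, `d_minor`, `d_equiv` (mm).
#' @export
isodose_geometry <- function(plane, level) {
  stopifnot(inherits(plane, "dose_plane"), level > 0, level < 1)
  m <- max(plane$values)
  cl <- grDevices::contourLines(plane$u, plane$v, plane$values, levels = level * m)
  if (length(cl) == 0) stop("no contour at this level", call. = FALSE)
  # keep closed loops (not touching the map boundary); take the largest
  eps <- 1e-6
  closed <- purrr::keep(cl, function(cc) {
    on_edge <- any(cc$x <= min(plane$u) + eps | cc$x >= max(plane$u) - eps |
                     cc$y <= min(plane$v) + eps | cc$y >= max(plane$v) - eps)
    !on_edge
  })
  if (length(closed) == 0) stop("contour at this level is open (touches the map edge)", call. = FALSE)
  spans <- purrr::map_dbl(closed, function(cc) diff(range(cc$x)) * diff(range(cc$y)))
  cc <- closed[[which.max(spans)]]
  theta <- seq(0, pi, length.out = 73)[-73]
  widths <- purrr::map_dbl(theta, function(a) {
    pr <- cc$x * cos(a) + cc$y * sin(a)
    max(pr) - min(pr)
  })
  d_major <- max(widths)
  d_minor <- min(widths)
  tibble::tibble(level = level, d_major = d_major, d_minor = d_minor,
                 d_equiv = sqrt(d_major * d_minor))
}

#' Symmetric percent difference between calculated and measured values
#'
#' `100 * (measured - calculated) / mean(calculated, measured)` -- the
#' relative-to-mean convention used for calculated-vs-measured dosimetric
#' comparisons. Antisymmetric under argument swap.
#'
#' @param calculated,measured Positive numeric vectors (recycled).
#' @return Percent difference(s).
#' @examples
#' percent_difference(0.605, 0.620)  # 2.45
#' @export
percent_difference <- function(calculated, measured) {
  if (any(calculated <= 0) || any(measured <= 0)) {
    stop("both inputs must be positive", call. = FALSE)
  }
  100 * (measured - calculated) / ((measured + calculated) / 2)
}

#' Maximum dose inside a spherical organ-at-risk
#'
#' @param grid A `dose_grid`.
#' @param center Length-3 vector, mm: center of the spherical structure.
#' @param radius Sphere radius, mm.
#' @param tolerance Fraction of the maximum defining the "receiving the
#'   maximum dose" shell (default 0.05, i.e. within 5 percent of the max).
#' @return A one-row tibble: `max_dose` (cGy) and `volume_cc` (cm^3) of the
#'   structure's voxels within `tolerance` of that maximum.
#' @export
oar_max_dose <- function(grid, center, radius, tolerance = 0.05) {
  stopifnot(inherits(grid, "dose_grid"), length(center) == 3, radius > 0)
  d2 <- outer(outer((grid$x - center[1])^2, (grid$y - center[2])^2, `+`),
              (grid$z - center[3])^2, `+`)
  inside <- d2 <= radius^2
  if (!any(inside)) stop("organ sphere does not intersect the dose grid", call. = FALSE)
  doses <- grid$values[inside]
  mx <- max(doses)
  vol <- sum(doses >= (1 - tolerance) * mx) * grid$spacing^3 / 1000
  tibble::tibble(max_dose = mx, volume_cc = vol)
}

#' Leaf-shift sensitivity study
#'
#' Evaluates the field output factor and the central-axis dose per MU of the
#' fVC field under small symmetric leaf shifts, for each beam preset and each
#' clinical setting, and reports percent changes relative to the unshifted
#' field -- the robustness test for leaf-position drift during arc delivery.
#'
#' @param presets List of [beam_preset()] objects (default both shipped
#'   energies).
#' @param shifts Leaf shifts in mm; must contain 0 (the reference).
#' @param settings Character vector of clinical settings among `"95/5"`
#'   (95 cm SSD / 5 cm depth) and `"90/10"`.
#' @return A tibble with one row per energy, setting and shift: `of`,
#'   `dose_per_mu`, `of_pct_change`, `dose_pct_change`, plus per-group
#'   standard deviations of the nonzero-shift percent changes in columns
#'   `of_sigma` and `dose_sigma`.
#' @export
leaf_shift_study <- function(presets = list(beam_preset("6FFF"), beam_preset("10FFF")),
                             shifts = c(-1, -0.5, 0, 0.5, 1),
                             settings = c("95/5", "90/10")) {
  if (!any(shifts == 0)) stop("shifts must include 0 as the reference", call. = FALSE)
  setting_phantom <- list("95/5" = phantom("slab", 50), "90/10" = phantom("slab", 100))
  rows <- purrr::map(presets, function(preset) {
    purrr::map(settings, function(setting) {
      phan <- setting_phantom[[setting]]
      purrr::map(shifts, function(sh) {
        fld <- fvc_field(sh)
        tibble::tibble(
          energy = preset$energy_label, setting = setting, shift = sh,
          of = field_output_factor(fld, preset, setting),
          dose_per_mu = point_dose(beam_geometry(), 1, fld, preset,
                                   c(0, 0, 0), phan)
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  rows |>
    dplyr::group_by(.data$energy, .data$setting) |>
    dplyr::mutate(
      of_pct_change = 100 * (.data$of / .data$of[.data$shift == 0] - 1),
      dose_pct_change = 100 * (.data$dose_per_mu / .data$dose_per_mu[.data$shift == 0] - 1),
      of_sigma = stats::sd(.data$of_pct_change[.data$shift != 0]),
      dose_sigma = stats::sd(.data$dose_pct_change[.data$shift != 0])
    ) |>
    dplyr::ungroup()
}
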