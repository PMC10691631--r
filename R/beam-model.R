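#' The fixed-virtual-cone MLC field
#'
#' Constructs the fixed 0.5 cm x 0.5 cm aperture defined by the two central
#' HDMLC leaf pairs at the isocenter plane, with the backup jaws at
#' 1.5 cm x 1.5 cm. A leaf-shift perturbation displaces both X-bank leaf
#' edges symmetrically: positive shifts open the aperture (width
#' `5 + 2 * leaf_shift` mm), negative shifts close it. The Y aperture (leaf
#' sides) is unaffected.
#'
#' @param leaf_shift Leaf-bank displacement in mm, `|leaf_shift| <= 2`.
#' @return An object of class `mlc_field`.
#' @examples
#' fvc_field()            # nominal 5 mm x 5 mm
#' fvc_field(-1)          # 3 mm x 5 mm perturbed aperture
#' @export
fvc_field <- function(leaf_shift = 0) {
  stopifnot(is.numeric(leaf_shift), length(leaf_shift) == 1)
  if (abs(leaf_shift) > 2) stop("|leaf_shift| must be <= 2 mm", call. = FALSE)
  x1 <- -2.5 - leaf_shift
  x2 <- 2.5 + leaf_shift
  if (x2 - x1 <= 0) stop("leaf shift closes the aperture (width <= 0)", call. = FALSE)
  structure(
    list(x1 = x1, x2 = x2, y1 = -2.5, y2 = 2.5,
         jaw_x = 7.5, jaw_y = 7.5, leaf_shift = leaf_shift),
    class = "mlc_field"
  )
}

#' @export
print.mlc_field <- function(x, ...) {
  cat(sprintf("<mlc_field> aperture %.1f x %.1f mm (leaf shift %+.1f mm), jaws %.0f x %.0f mm\n",
              x$x2 - x$x1, x$y2 - x$y1, x$leaf_shift, 2 * x$jaw_x, 2 * x$jaw_y))
  invisible(x)
}

preset_file <- function(energy) {
  fn <- switch(energy,
               "6FFF" = "preset_6fff.yaml",
               "10FFF" = "preset_10fff.yaml",
               stop("unknown energy label: ", energy, call. = FALSE))
  system.file("extdata", fn, package = "fvcdose", mustWork = TRUE)
}

#' Load an analytic beam preset
#'
#' A beam preset is the analytic stand-in for a commissioned linac beam
#' model: fluence-edge blur (`sigma_penumbra`), MLC/jaw transmissions,
#' effective edge offsets for the rounded leaf ends (X, leaf travel) and the
#' leaf sides (Y), a tissue-maximum-ratio (TMR) table, small-field output
#' factor tables for the two clinical settings (95 cm SSD / 5 cm depth and
#' 90 cm SSD / 10 cm depth, both at 100 cm SAD), and the calibration dose per
#' monitor unit for the nominal fVC field at the 95/5 reference. Presets for
#' the `"6FFF"` and `"10FFF"` beams ship with the package as YAML files.
#'
#' @param energy `"6FFF"` or `"10FFF"`, or a path to a preset YAML file.
#' @return An object of class `beam_preset`.
#' @examples
#' p <- beam_preset("10FFF")
#' p$dmu_cal
#' @export
beam_preset <- function(energy = c("10FFF", "6FFF")) {
  if (length(energy) == 1 && file.exists(energy)) {
    path <- energy
  } else {
    energy <- match.arg(energy)
    path <- preset_file(energy)
  }
  raw <- yaml::read_yaml(path)
  validate_beam_preset(raw)
}

validate_beam_preset <- function(raw) {
  req <- c("energy_label", "sigma_penumbra", "mlc_transmission", "jaw_transmission",
           "leaf_end_offset", "leaf_side_offset", "tmr", "of_tables", "dmu_cal",
           "max_dose_rate")
  missing <- setdiff(req, names(raw))
  if (length(missing)) stop("preset missing fields: ", paste(missing, collapse = ", "), call. = FALSE)
  tmr <- tibble::tibble(depth = as.numeric(raw$tmr$depth), value = as.numeric(raw$tmr$value))
  if (is.unsorted(tmr$depth, strictly = TRUE)) stop("TMR depths must be strictly increasing", call. = FALSE)
  i_max <- which.max(tmr$value)
  if (any(diff(tmr$value[i_max:nrow(tmr)]) >= 0)) {
    stop("TMR must decrease monotonically beyond its peak", call. = FALSE)
  }
  raw$of_tables <- lapply(raw$of_tables, function(tab) {
    list(size = as.numeric(unlist(tab$size)), value = as.numeric(unlist(tab$value)))
  })
  raw$tmr <- list(depth = as.numeric(unlist(raw$tmr$depth)),
                  value = as.numeric(unlist(raw$tmr$value)))
  for (nm in names(raw$of_tables)) {
    tab <- raw$of_tables[[nm]]
    if (is.unsorted(tab$size, strictly = TRUE) || is.unsorted(tab$value, strictly = TRUE)) {
      stop("output-factor table '", nm, "' must be strictly increasing in size and value", call. = FALSE)
    }
    if (any(tab$value <= 0) || any(tab$value > 1.2)) {
      stop("output factors must lie in (0, 1.2]", call. = FALSE)
    }
  }
  for (tr in c("mlc_transmission", "jaw_transmission")) {
    if (raw[[tr]] < 0 || raw[[tr]] >= 0.05) stop(tr, " must lie in [0, 0.05)", call. = FALSE)
  }
  p <- raw
  p$tmr <- tmr
  p$of_tables <- lapply(raw$of_tables, function(tab) {
    tibble::tibble(size = as.numeric(tab$size), value = as.numeric(tab$value))
  })
  # monotone cubic interpolators, clamped at the table ends
  p$tmr_fun <- stats::splinefun(tmr$depth, tmr$value, method = "monoH.FC")
  p$of_funs <- lapply(p$of_tables, function(tab) {
    f <- stats::splinefun(tab$size, tab$value, method = "monoH.FC")
    rng <- range(tab$size)
    function(s) f(pmin(pmax(s, rng[1]), rng[2]))
  })
  class(p) <- "beam_preset"
  p
}

#' @export
print.beam_preset <- function(x, ...) {
  cat(sprintf("<beam_preset> %s: sigma %.2f mm, edge offsets %.2f/%.2f mm (X/Y), dmu_cal %.3f cGy/MU\n",
              x$energy_label, x$sigma_penumbra, x$leaf_end_offset, x$leaf_side_offset, x$dmu_cal))
  invisible(x)
}

#' Tissue-maximum ratio
#'
#' @param preset A [beam_preset()].
#' @param depth Depth(s) in mm.
#' @return TMR value(s); clamped to the table's depth range.
#' @export
tmr <- function(preset, depth) {
  stopifnot(inherits(preset, "beam_preset"))
  rng <- range(preset$tmr$depth)
  preset$tmr_fun(pmin(pmax(depth, rng[1]), rng[2]))
}

# Single-axis aperture edge profile: error-function-smoothed top hat between
# the effective edges, in [0, 1].
edge_profile <- function(x, e1, e2, sigma) {
  stats::pnorm((e2 - x) / sigma) - stats::pnorm((e1 - x) / sigma)
}

#' Relative in-air fluence of an MLC field at the isocenter plane
#'
#' Separable product of per-axis error-function edge profiles between the
#' effective field edges (the geometric leaf positions pushed outward by the
#' preset's rounded-leaf-end offset on X and leaf-side offset on Y), blurred
#' with `sigma_penumbra`, with an `mlc_transmission` floor inside the jaw
#' opening and `jaw_transmission` outside it.
#'
#' @param field An [fvc_field()].
#' @param preset A [beam_preset()].
#' @param x_bev,y_bev Coordinates at the isocenter plane, mm (vectorized;
#'   recycled to a common length). X is the leaf-travel axis.
#' @return Relative fluence values in `[jaw_transmission, 1]`.
#' @export
fluence <- function(field, preset, x_bev, y_bev) {
  stopifnot(inherits(field, "mlc_field"), inherits(preset, "beam_preset"))
  n <- max(length(x_bev), length(y_bev))
  x <- rep_len(x_bev, n)
  y <- rep_len(y_bev, n)
  s <- preset$sigma_penumbra
  px <- edge_profile(x, field$x1 - preset$leaf_end_offset, field$x2 + preset$leaf_end_offset, s)
  py <- edge_profile(y, field$y1 - preset$leaf_side_offset, field$y2 + preset$leaf_side_offset, s)
  tm <- preset$mlc_transmission
  val <- tm + (1 - tm) * px * py
  outside <- abs(x) > field$jaw_x | abs(y) > field$jaw_y
  val[outside] <- preset$jaw_transmission
  val
}

#' Effective equivalent-square field size of an aperture
#'
#' `sqrt(width_x_eff * width_y_eff)` where the effective widths include the
#' preset's edge offsets on each side.
#'
#' @inheritParams fluence
#' @return Equivalent square size in mm.
#' @export
equivalent_square <- function(field, preset) {
  wx <- (field$x2 - field$x1) + 2 * preset$leaf_end_offset
  wy <- (field$y2 - field$y1) + 2 * preset$leaf_side_offset
  sqrt(wx * wy)
}

#' Small-field output factor of an MLC aperture
#'
#' Interpolates the preset's output-factor table (monotone cubic) at the
#' aperture's effective equivalent-square size. Sizes outside the table range
#' are clamped with a warning.
#'
#' @inheritParams fluence
#' @param setting Clinical setting whose table to use: `"95/5"` (95 cm SSD,
#'   5 cm depth; the calibration reference) or `"90/10"`.
#' @return Scalar output factor.
#' @examples
#' field_output_factor(fvc_field(), beam_preset("10FFF"))  # 0.550
#' @export
field_output_factor <- function(field, preset, setting = "95/5") {
  stopifnot(inherits(field, "mlc_field"), inherits(preset, "beam_preset"))
  if (!setting %in% names(preset$of_funs)) {
    stop("preset has no output-factor table for setting ", setting, call. = FALSE)
  }
  if (field$x2 > field$jaw_x || field$x1 < -field$jaw_x ||
      field$y2 > field$jaw_y || field$y1 < -field$jaw_y) {
    stop("aperture extends beyond the jaw opening", call. = FALSE)
  }
  s <- equivalent_square(field, preset)
  rng <- range(preset$of_tables[[setting]]$size)
  if (s < rng[1] || s > rng[2]) {
    warning("equivalent square size ", signif(s, 4),
            " mm outside output-factor table range; clamped", call. = FALSE)
  }
  preset$of_funs[[setting]](s)
}
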