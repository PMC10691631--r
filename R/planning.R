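#' Arc ensemble treatment plan
#'
#' A plan is a set of partial non-coplanar arcs of the fixed-virtual-cone
#' field. Each arc row carries its couch and collimator angle, gantry start
#' and stop, rotation direction and relative monitor-unit weight; weights are
#' normalized to sum to one on construction.
#'
#' @param arcs Data frame with columns `couch`, `collimator`, `gantry_start`,
#'   `gantry_stop`, `direction` (`"CW"` or `"CCW"`) and `weight`.
#' @param field An [fvc_field()] (default nominal).
#' @param energy Beam preset label, `"10FFF"` or `"6FFF"`.
#' @param total_mu Total plan monitor units (ignored when
#'   `normalization = "max_dose"`, where it is rescaled so the maximum voxel
#'   dose equals `prescription`).
#' @param prescription Prescription dose in cGy (clinically 7000-8000 cGy for
#'   a single-fraction trigeminal neuralgia treatment).
#' @param normalization `"max_dose"` (rescale so max dose = prescription) or
#'   `"fixed_mu"` (deliver `total_mu` as given).
#' @return An object of class `fvc_plan`.
#' @export
fvc_plan <- function(arcs, field = fvc_field(), energy = "10FFF",
                     total_mu = 10000, prescription = 7500,
                     normalization = c("max_dose", "fixed_mu")) {
  normalization <- match.arg(normalization)
  arcs <- tibble::as_tibble(arcs)
  req <- c("couch", "collimator", "gantry_start", "gantry_stop", "direction", "weight")
  missing <- setdiff(req, names(arcs))
  if (length(missing)) stop("arcs missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(arcs) < 1 || nrow(arcs) > 20) stop("plans must have 1-20 arcs", call. = FALSE)
  if (!all(arcs$direction %in% c("CW", "CCW"))) stop("direction must be 'CW' or 'CCW'", call. = FALSE)
  if (any(arcs$weight <= 0)) stop("arc weights must be positive", call. = FALSE)
  spans <- arc_span(arcs)
  if (any(spans < 1 | spans > 360)) stop("arc spans must lie in [1, 360] degrees", call. = FALSE)
  arcs$weight <- arcs$weight / sum(arcs$weight)
  structure(
    list(arcs = arcs, field = field, energy = energy, total_mu = total_mu,
         prescription = prescription, normalization = normalization),
    class = "fvc_plan"
  )
}

# signed span traversed along the stated direction, in (0, 360]
arc_span <- function(arcs) {
  span <- ifelse(arcs$direction == "CW",
                 (arcs$gantry_stop - arcs$gantry_start) %% 360,
                 (arcs$gantry_start - arcs$gantry_stop) %% 360)
  ifelse(span == 0, 360, span)
}

#' @export
print.fvc_plan <- function(x, ...) {
  cat(sprintf("<fvc_plan> %d arcs, %s, Rx %.0f cGy, normalization %s\n",
              nrow(x$arcs), x$energy, x$prescription, x$normalization))
  print(x$arcs, n = nrow(x$arcs))
  invisible(x)
}

#' @export
tidy.fvc_plan <- function(x, ...) {
  dplyr::mutate(x$arcs, span = arc_span(x$arcs), .before = "weight")
}

#' @export
glance.fvc_plan <- function(x, ...) {
  tibble::tibble(
    n_arcs = nrow(x$arcs), energy = x$energy, prescription = x$prescription,
    total_mu = x$total_mu, normalization = x$normalization,
    aperture_mm = x$field$x2 - x$field$x1
  )
}

# Integral of |sin(theta)| (theta in degrees) from 0 to theta, in units where
# the integral over one half-turn is 2 (i.e. radians of the antiderivative).
abs_sin_integral <- function(theta_deg) {
  k <- floor(theta_deg / 180)
  rem <- theta_deg - 180 * k
  2 * k + (1 - cos(deg2rad(rem)))
}

#' Discretize an arc into sine-weighted control points
#'
#' Splits the arc into gantry bins of at most `delta_gantry` degrees and
#' assigns each control point (bin midpoint) the monitor units proportional
#' to the exact integral of `|sin(gantry)|` over its bin, the gantry angle
#' being measured from the vertical (gantry 0). Vertex beams therefore get
#' zero dose per degree, and in the large-arc, full-sphere limit the
#' MU-weighted beam directions become uniform per unit solid angle -- the
#' condition for a spherical dose distribution. Control-point MUs are
#' renormalized to sum exactly to the arc's MU share.
#'
#' @param arc One-row data frame (or list) with the [fvc_plan()] arc columns.
#' @param delta_gantry Gantry spacing in degrees, in `(0, 10]`.
#' @param mu Total monitor units of this arc.
#' @return A tibble of control points: `gantry`, `couch`, `collimator`, `mu`.
#' @export
sine_weights <- function(arc, delta_gantry = 2, mu = 1) {
  if (!(delta_gantry > 0 && delta_gantry <= 10)) {
    stop("delta_gantry must lie in (0, 10] degrees", call. = FALSE)
  }
  span <- arc_span(tibble::as_tibble(arc[c("gantry_start", "gantry_stop", "direction")]))
  n <- ceiling(span / delta_gantry)
  step <- span / n
  sgn <- if (arc$direction == "CW") 1 else -1
  edges <- arc$gantry_start + sgn * step * (0:n)
  mids <- (edges[-1] + edges[-(n + 1)]) / 2
  w <- abs(abs_sin_integral(pmax(edges[-1], edges[-(n + 1)])) -
             abs_sin_integral(pmin(edges[-1], edges[-(n + 1)])))
  if (sum(w) <= 1e-12) stop("zero-weight arc: |sin(gantry)| vanishes over the whole span", call. = FALSE)
  tibble::tibble(
    gantry = mids %% 360,
    couch = arc$couch,
    collimator = arc$collimator,
    mu = mu * w / sum(w)
  )
}

#' Discretize a whole plan into control points
#'
#' @param plan An [fvc_plan()].
#' @param delta_gantry Gantry spacing in degrees (default 2).
#' @param total_mu Override for the plan's total MU (used internally by dose
#'   normalization).
#' @return A tibble of control points with an `arc` index column.
#' @export
plan_control_points <- function(plan, delta_gantry = 2, total_mu = plan$total_mu) {
  stopifnot(inherits(plan, "fvc_plan"))
  purrr::list_rbind(purrr::imap(
    split(plan$arcs, seq_len(nrow(plan$arcs))),
    function(arc, i) {
      cp <- sine_weights(arc, delta_gantry, mu = arc$weight * total_mu)
      dplyr::mutate(cp, arc = as.integer(i), .before = 1)
    }
  ))
}

#' Default trigeminal-neuralgia plan generator
#'
#' Generates the default arc ensemble used throughout the package: 10-14
#' non-coplanar partial arcs of the nominal fVC field with couch angles
#' spread over (-90, 90) degrees, gantry spans of 30-90 degrees placed as
#' anterior vertex arcs crossing gantry 0 (avoiding posterior-through-couch
#' delivery and keeping beams off the posteriorly located brainstem),
#' collimator angles cycled over 0-90 degrees, and alternating CW/CCW
#' rotation. Small seeded jitters de-align couch angles and span centers;
#' the result is deterministic for a given seed. Arcs on alternating sides of
#' gantry 0 keep a minimum gantry magnitude of about 9 degrees so no two
#' control-point beam directions nearly coincide.
#'
#' @param n_arcs Number of arcs, 10-14.
#' @param energy Beam preset label.
#' @param prescription Prescription dose in cGy.
#' @param seed Integer seed controlling the jitters.
#' @return An [fvc_plan()].
#' @examples
#' plan <- default_tgn_plan(12, seed = 1)
#' tidy(plan)
#' @export
default_tgn_plan <- function(n_arcs = 12, energy = "10FFF", prescription = 7500, seed = 1) {
  if (n_arcs < 10 || n_arcs > 14) stop("n_arcs must lie in [10, 14]", call. = FALSE)
  widths <- rep_len(c(30, 32, 36, 30, 34, 38), n_arcs)
  withr::with_seed(seed, {
    couch <- seq(-85, 85, length.out = n_arcs) + stats::runif(n_arcs, -2, 2)
    min_edge <- 8 + stats::runif(n_arcs, 0, 2)
  })
  side <- rep_len(c(1, -1), n_arcs)
  start <- side * min_edge
  stop <- side * (min_edge + widths)
  arcs <- tibble::tibble(
    couch = couch,
    collimator = rep_len(seq(0, 90, by = 15), n_arcs),
    gantry_start = ifelse(side > 0, start, start) %% 360,
    gantry_stop = stop %% 360,
    direction = rep_len(c("CW", "CCW"), n_arcs),
    weight = 1
  )
  # traverse outward from the small-|gantry| edge along the stated direction
  flip <- (arcs$direction == "CW" & side < 0) | (arcs$direction == "CCW" & side > 0)
  tmp <- arcs$gantry_start[flip]
  arcs$gantry_start[flip] <- arcs$gantry_stop[flip]
  arcs$gantry_stop[flip] <- tmp
  fvc_plan(arcs, field = fvc_field(), energy = energy, prescription = prescription)
}

# unit beam directions (source -> isocenter) for control points
cp_directions <- function(cps) {
  g <- deg2rad(cps$gantry)
  c <- deg2rad(cps$couch)
  cbind(-cos(c) * sin(g), sin(c) * sin(g), -cos(g))
}

#' Uniformity of the MU-weighted beam-direction density
#'
#' Bins the unit beam directions of a discretized plan into equal-area cells
#' on the sphere, accumulates monitor units per cell, and returns the
#' coefficient of variation across the cells of the hemisphere(s) the plan
#' reaches (upper, lower, or both, judged by the sign of the directions'
#' z-components). A perfectly uniform direction density has CV 0.
#'
#' @param plan An [fvc_plan()] or a control-point tibble from
#'   [plan_control_points()].
#' @param n_bins Approximate number of equal-area bins on the full sphere.
#' @param delta_gantry Discretization used when `plan` is an `fvc_plan`.
#' @return A one-row tibble: `cv`, `n_bins_covered`, `n_cp`.
#' @export
direction_density <- function(plan, n_bins = 60, delta_gantry = 2) {
  cps <- if (inherits(plan, "fvc_plan")) plan_control_points(plan, delta_gantry) else plan
  d <- cp_directions(cps)
  n_band <- max(2, round(sqrt(n_bins)))
  n_phi <- max(1, round(n_bins / n_band))
  iz <- pmin(pmax(ceiling((d[, 3] + 1) / 2 * n_band), 1), n_band)
  phi <- atan2(d[, 2], d[, 1])
  ip <- pmin(pmax(ceiling((phi + pi) / (2 * pi) * n_phi), 1), n_phi)
  cell <- (iz - 1) * n_phi + ip
  mu_cell <- rep(0, n_band * n_phi)
  acc <- tapply(cps$mu, cell, sum)
  mu_cell[as.integer(names(acc))] <- acc
  hemis <- c(lower = any(d[, 3] < 0), upper = any(d[, 3] > 0))
  z_lo <- rep(seq(-1, 1 - 2 / n_band, by = 2 / n_band), each = n_phi)
  keep <- (hemis[["lower"]] & z_lo < 0) | (hemis[["upper"]] & z_lo >= 0)
  vals <- mu_cell[keep]
  tibble::tibble(
    cv = stats::sd(vals) / mean(vals),
    n_bins_covered = sum(keep),
    n_cp = nrow(cps)
  )
}
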