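#' Beam geometry at fixed source-axis distance
#'
#' Bundles the gantry, collimator and couch angles of an isocentric beam
#' together with the source-axis distance (SAD). The fixed room frame follows
#' an IEC 61217-style convention: `X` points to the patient's left, `Y`
#' superior, `Z` up, with the isocenter at the origin. At gantry 0 the source
#' sits on `+Z`; positive gantry rotation swings the source towards `+X`.
#' Couch rotation turns the patient about `+Z`, which is implemented as the
#' equivalent rotation of the beam by the negative couch angle so the dose
#' grid never moves.
#'
#' @param gantry Gantry angle in degrees; normalized to `[0, 360)`.
#' @param collimator Collimator angle in degrees; normalized to `[0, 360)`.
#' @param couch Couch angle in degrees, must lie in `[-90, 90]` after
#'   wrapping to `(-180, 180]`.
#' @param sad Source-axis distance in mm (default 1000).
#' @return An object of class `beam_geometry`.
#' @examples
#' g <- beam_geometry(gantry = 90, couch = 0)
#' source_position(g)
#' @export
beam_geometry <- function(gantry = 0, collimator = 0, couch = 0, sad = 1000) {
  stopifnot(is.numeric(gantry), is.numeric(collimator), is.numeric(couch),
            length(gantry) == 1, length(collimator) == 1, length(couch) == 1)
  if (!is.numeric(sad) || length(sad) != 1 || sad <= 0) {
    stop("`sad` must be a single positive length in mm", call. = FALSE)
  }
  couch <- ((couch + 180) %% 360) - 180
  if (couch < -90 || couch > 90) {
    stop("`couch` must lie in [-90, 90] degrees", call. = FALSE)
  }
  structure(
    list(
      gantry = gantry %% 360,
      collimator = collimator %% 360,
      couch = couch,
      sad = sad
    ),
    class = "beam_geometry"
  )
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> gantry %.2f, collimator %.2f, couch %.2f, SAD %.0f mm\n",
              x$gantry, x$collimator, x$couch, x$sad))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180

# Orthonormal beam basis in the (couch-rotated) patient frame.
# Columns: e_x, e_y, e_z with e_z the unit vector from isocenter to source.
beam_basis <- function(geom) {
  g <- deg2rad(geom$gantry)
  c <- deg2rad(geom$couch)
  ry <- matrix(c(cos(g), 0, -sin(g),
                 0,      1, 0,
                 sin(g), 0, cos(g)), nrow = 3)
  rz <- matrix(c(cos(c),  sin(c), 0,
                 -sin(c), cos(c), 0,
                 0,       0,      1), nrow = 3)
  # patient-frame beam = Rz(-couch) %*% Ry(gantry)
  rzm <- t(rz) # Rz(-c)
  rzm %*% ry
}

#' Source position in the patient frame
#'
#' @param geom A [beam_geometry()].
#' @return Numeric length-3 vector, mm, with the isocenter at the origin and
#'   `|result| == sad`.
#' @examples
#' source_position(beam_geometry(gantry = 0))   # c(0, 0, 1000)
#' @export
source_position <- function(geom) {
  stopifnot(inherits(geom, "beam_geometry"))
  as.numeric(geom$sad * beam_basis(geom)[, 3])
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3) stop("points must be length-3 or an n x 3 matrix", call. = FALSE)
    points <- matrix(points, nrow = 1)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must have 3 columns (x, y, z in mm)", call. = FALSE)
  storage.mode(points) <- "double"
  points
}

#' Express room-frame points in beam's-eye-view coordinates
#'
#' `z_along` is the distance from the source along the central axis
#' (`z_along == sad` at the isocenter); `x_bev`/`y_bev` are transverse offsets
#' in the plane at that distance, after applying the collimator rotation about
#' the central axis.
#'
#' @param points Length-3 vector or `n x 3` matrix of room-frame points (mm).
#' @param geom A [beam_geometry()].
#' @return A tibble with columns `x_bev`, `y_bev`, `z_along` (mm).
#' @export
to_beam_frame <- function(points, geom) {
  stopifnot(inherits(geom, "beam_geometry"))
  p <- as_point_matrix(points)
  b <- beam_basis(geom)
  k <- deg2rad(geom$collimator)
  x_b <- cos(k) * b[, 1] + sin(k) * b[, 2]
  y_b <- -sin(k) * b[, 1] + cos(k) * b[, 2]
  axis <- -b[, 3] # central axis direction, source -> isocenter
  s <- geom$sad * b[, 3]
  v <- sweep(p, 2, s)
  out <- tibble::tibble(
    x_bev = as.numeric(v %*% x_b),
    y_bev = as.numeric(v %*% y_b),
    z_along = as.numeric(v %*% axis)
  )
  if (any(abs(out$z_along) < 1e-9)) {
    stop("degenerate projection: point at the source plane (z_along = 0)", call. = FALSE)
  }
  out
}

#' Inverse of [to_beam_frame()]
#'
#' @param bev Tibble or data frame with columns `x_bev`, `y_bev`, `z_along`.
#' @inheritParams to_beam_frame
#' @return `n x 3` matrix of room-frame points (mm).
#' @export
from_beam_frame <- function(bev, geom) {
  stopifnot(inherits(geom, "beam_geometry"))
  b <- beam_basis(geom)
  k <- deg2rad(geom$collimator)
  x_b <- cos(k) * b[, 1] + sin(k) * b[, 2]
  y_b <- -sin(k) * b[, 1] + cos(k) * b[, 2]
  axis <- -b[, 3]
  s <- geom$sad * b[, 3]
  p <- outer(bev$x_bev, x_b) + outer(bev$y_bev, y_b) + outer(bev$z_along, axis)
  sweep(p, 2, -s)
}

#' Water phantom specification
#'
#' Either a semi-infinite slab of water below a horizontal surface (`slab`,
#' `size` = surface height above the isocenter in mm) or a water sphere
#' centered at the isocenter (`sphere`, `size` = radius in mm). The sphere
#' mode stands in for the roughly cranial geometry of an isocentric
#' radiosurgery delivery, where the source-surface distance changes with beam
#' angle while the SAD stays fixed.
#'
#' @param shape `"slab"` or `"sphere"`.
#' @param size Positive length in mm (slab surface height, or sphere radius).
#' @export
phantom <- function(shape = c("slab", "sphere"), size = 50) {
  shape <- match.arg(shape)
  if (!is.numeric(size) || length(size) != 1 || size <= 0) {
    stop("`size` must be a single positive length in mm", call. = FALSE)
  }
  structure(list(shape = shape, size = size, medium = "water"), class = "phantom")
}

#' Radiological depth and SSD along the source ray
#'
#' Traces the ray from the source through each point and returns the
#' water-equivalent depth from the phantom surface to the point together with
#' the source-surface distance (SSD) along that ray. The phantom is water
#' only, so the water-equivalent path equals the geometric path inside the
#' phantom.
#'
#' @inheritParams to_beam_frame
#' @param phan A [phantom()]. Points must be inside the phantom.
#' @return A tibble with columns `depth` and `ssd` (mm).
#' @examples
#' # 95 cm SSD / 5 cm depth reference setting
#' ray_depth(c(0, 0, 0), beam_geometry(gantry = 0), phantom("slab", 50))
#' @export
ray_depth <- function(points, geom, phan) {
  stopifnot(inherits(geom, "beam_geometry"), inherits(phan, "phantom"))
  p <- as_point_matrix(points)
  s <- source_position(geom)
  v <- sweep(p, 2, s)
  dist <- sqrt(rowSums(v^2))
  u <- v / dist
  if (phan$shape == "slab") {
    inside <- p[, 3] <= phan$size + 1e-9
    if (!all(inside)) stop("point outside phantom (above slab surface)", call. = FALSE)
    if (any(u[, 3] >= -1e-12)) {
      stop("ray misses phantom: beam must descend through the slab surface", call. = FALSE)
    }
    t_entry <- (phan$size - s[3]) / u[, 3]
    if (any(t_entry < 0)) stop("ray misses phantom surface", call. = FALSE)
  } else {
    r2 <- rowSums(p^2)
    if (any(r2 > phan$size^2 + 1e-6)) stop("point outside phantom sphere", call. = FALSE)
    b <- as.numeric(u %*% s)
    disc <- b^2 - (sum(s^2) - phan$size^2)
    if (any(disc <= 0)) stop("ray misses phantom sphere", call. = FALSE)
    t_entry <- -b - sqrt(disc)
    if (any(t_entry < 0)) stop("source inside phantom sphere is not supported", call. = FALSE)
  }
  tibble::tibble(depth = dist - t_entry, ssd = t_entry)
}
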