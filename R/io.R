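#' Write / read a plan as YAML
#'
#' @param plan An [fvc_plan()].
#' @param path File path.
#' @return `read_fvc_plan` returns an [fvc_plan()]; `write_fvc_plan` returns
#'   `path` invisibly.
#' @export
write_fvc_plan <- function(plan, path) {
  stopifnot(inherits(plan, "fvc_plan"))
  yaml::write_yaml(list(
    energy = plan$energy,
    total_mu = plan$total_mu,
    prescription = plan$prescription,
    normalization = plan$normalization,
    leaf_shift = plan$field$leaf_shift,
    arcs = lapply(seq_len(nrow(plan$arcs)), function(i) as.list(plan$arcs[i, ]))
  ), path)
  invisible(path)
}

#' @rdname write_fvc_plan
#' @export
read_fvc_plan <- function(path) {
  raw <- yaml::read_yaml(path)
  arcs <- purrr::list_rbind(purrr::map(raw$arcs, tibble::as_tibble))
  fvc_plan(arcs, field = fvc_field(raw$leaf_shift %||% 0), energy = raw$energy,
           total_mu = raw$total_mu, prescription = raw$prescription,
           normalization = raw$normalization)
}

plane_header <- function(plane, seed = NULL) {
  c(sprintf("# fvcdose %s", as.character(utils::packageVersion("fvcdose"))),
    sprintf("# orientation: %s  offset_mm: %g", plane$orientation, plane$offset),
    if (!is.null(seed)) sprintf("# seed: %d", seed),
    sprintf("# u_mm: %s", paste(signif(plane$u, 8), collapse = " ")),
    sprintf("# v_mm: %s", paste(signif(plane$v, 8), collapse = " ")))
}

#' Write / read a planar dose map as a CSV matrix with a header block
#'
#' Rows follow `u`, columns follow `v`; the commented header records the
#' coordinates, orientation and (optionally) the seed.
#'
#' @param plane A `dose_plane`.
#' @param path File path.
#' @param seed Optional integer recorded in the header.
#' @export
write_dose_plane <- function(plane, path, seed = NULL) {
  stopifnot(inherits(plane, "dose_plane"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(plane_header(plane, seed), con)
  utils::write.table(plane$values, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_plane
#' @export
read_dose_plane <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  u <- scan(text = sub("^# u_mm: ", "", grep("^# u_mm:", hdr, value = TRUE)), quiet = TRUE)
  v <- scan(text = sub("^# v_mm: ", "", grep("^# v_mm:", hdr, value = TRUE)), quiet = TRUE)
  vals <- as.matrix(utils::read.table(text = lines[!grepl("^#", lines)], sep = ","))
  dimnames(vals) <- NULL
  orient <- sub("^# orientation: (\\S+).*", "\\1", grep("^# orientation:", hdr, value = TRUE))
  new_dose_plane(vals, u, v, c("u", "v"), orient)
}

#' Write a 3D dose grid
#'
#' Either long-format CSV (`x, y, z, dose`) or a simple voxel format: a text
#' header (dims, spacing, origin, units) followed by the doses as doubles in
#' column-major (x-fastest) order.
#'
#' @param grid A `dose_grid`.
#' @param path File path.
#' @param format `"csv"` or `"voxel"`.
#' @export
write_dose_grid <- function(grid, path, format = c("csv", "voxel")) {
  stopifnot(inherits(grid, "dose_grid"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as_tibble.dose_grid(grid), path, row.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- sprintf("fvcdose-voxel dims %d %d %d spacing %g origin %g %g %g units cGy\n",
                   length(grid$x), length(grid$y), length(grid$z), grid$spacing,
                   grid$x[1], grid$y[1], grid$z[1])
    writeChar(hdr, con, eos = NULL)
    writeBin(as.numeric(grid$values), con, size = 8)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
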