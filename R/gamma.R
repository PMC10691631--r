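#' Gamma-index acceptance criteria
#'
#' Global gamma criteria for planar dose QA: dose difference as a percent of
#' the reference map's global maximum, distance-to-agreement in mm, and a
#' low-dose threshold (percent of the reference maximum) below which points
#' are excluded from scoring. The clinical defaults here are 3 percent / 1 mm
#' for field-by-field comparisons and 2 percent / 1 mm for cumulative plan
#' doses, both with a 10 percent threshold.
#'
#' @param dose_percent Dose-difference criterion, percent of the global max.
#' @param dta Distance-to-agreement criterion, mm.
#' @param threshold_percent Low-dose exclusion threshold, percent of max.
#' @return A `gamma_criteria` object.
#' @export
gamma_criteria <- function(dose_percent = 3, dta = 1, threshold_percent = 10) {
  stopifnot(dose_percent > 0, dta > 0, threshold_percent > 0)
  structure(
    list(dose_percent = dose_percent, dta = dta,
         threshold_percent = threshold_percent, normalization = "global_max"),
    class = "gamma_criteria"
  )
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %g%%/%g mm, %g%% threshold (global)\n",
              x$dose_percent, x$dta, x$threshold_percent))
  invisible(x)
}

# Shared gamma engine. The evaluated map is bilinearly resampled onto a fine
# lattice (step mm) anchored at the reference origin; for each scored
# reference point the minimization searches lattice nodes within radius
# dta * gamma0, where gamma0 is the gamma at zero spatial offset -- an exact
# pruning bound, since any candidate farther away already exceeds gamma0
# through its distance term alone.
gamma_engine <- function(reference, evaluated, criteria, step, refine = 0) {
  stopifnot(inherits(reference, "dose_plane"), inherits(evaluated, "dose_plane"),
            inherits(criteria, "gamma_criteria"))
  d_max <- max(reference$values)
  if (d_max <= 0) stop("empty comparison: reference maximum dose is zero", call. = FALSE)
  if (min(evaluated$u) > max(reference$u) || max(evaluated$u) < min(reference$u) ||
      min(evaluated$v) > max(reference$v) || max(evaluated$v) < min(reference$v)) {
    stop("no overlap between reference and evaluated coordinates", call. = FALSE)
  }
  delta_d <- criteria$dose_percent / 100 * d_max
  dta <- criteria$dta
  # a vanishing DTA collapses the search to (near) zero offset; keep the
  # lattice at a sane resolution
  span <- max(diff(range(reference$u, evaluated$u)),
              diff(range(reference$v, evaluated$v)))
  step <- max(step, span / 2000)

  # fine lattice covering the evaluated extent, anchored at the reference grid
  u0 <- min(reference$u); v0 <- min(reference$v)
  fu <- seq(u0 + step * floor((min(evaluated$u) - u0) / step),
            max(evaluated$u) + step / 2, by = step)
  fv <- seq(v0 + step * floor((min(evaluated$v) - v0) / step),
            max(evaluated$v) + step / 2, by = step)
  fine <- outer(fu, fv, function(uu, vv) interp_plane(evaluated, uu, vv))

  ref_tab <- as_tibble.dose_plane(reference)
  scored <- ref_tab$dose >= criteria$threshold_percent / 100 * d_max
  gam <- rep(NA_real_, nrow(ref_tab))

  # reference-point lattice indices (reference grids are step-aligned in
  # practice; rounding error is at most step/2)
  riu <- round((ref_tab$u - fu[1]) / step) + 1L
  riv <- round((ref_tab$v - fv[1]) / step) + 1L

  # candidate offsets sorted by radius
  max_r_cells <- ceiling(max(diff(range(fu)), diff(range(fv))) / step)
  for (j in which(scored)) {
    dr <- ref_tab$dose[j]
    iu <- riu[j]; iv <- riv[j]
    ev0 <- if (iu >= 1 && iu <= length(fu) && iv >= 1 && iv <= length(fv)) {
      fine[iu, iv]
    } else NA_real_
    g0 <- if (is.na(ev0)) Inf else abs(ev0 - dr) / delta_d
    if (is.finite(g0) && g0 == 0) { gam[j] <- 0; next }
    r_cells <- min(ceiling(g0 * dta / step), max_r_cells)
    du <- seq.int(max(1L, iu - r_cells), min(length(fu), iu + r_cells)) - iu
    dv <- seq.int(max(1L, iv - r_cells), min(length(fv), iv + r_cells)) - iv
    r2 <- outer((du * step)^2, (dv * step)^2, `+`)
    ev <- fine[iu + du, iv + dv, drop = FALSE]
    g2 <- r2 / dta^2 + ((ev - dr) / delta_d)^2
    best <- which.min(g2)
    g2min <- g2[best]
    if (refine > 0) {
      # second stage: densify around the best coarse node and around the
      # zero-offset node (shallow minima near zero offset can undercut a
      # distant coarse node between lattice points)
      bu <- du[(best - 1) %% length(du) + 1] * step
      bv <- dv[(best - 1) %/% length(du) + 1] * step
      off <- seq(-2 * step, 2 * step, by = step / refine)
      cand <- rbind(expand.grid(ou = bu + off, ov = bv + off),
                    expand.grid(ou = off, ov = off))
      evf <- interp_plane(evaluated,
                          ref_tab$u[j] + cand$ou, ref_tab$v[j] + cand$ov)
      g2f <- (cand$ou^2 + cand$ov^2) / dta^2 + ((evf - dr) / delta_d)^2
      g2min <- min(g2min, g2f, na.rm = TRUE)
    }
    gam[j] <- sqrt(g2min)
  }
  structure(
    list(
      gamma = matrix(gam, nrow = length(reference$u)),
      u = reference$u, v = reference$v,
      passing_rate = 100 * mean(gam[scored] <= 1 + 1e-12, na.rm = TRUE),
      n_evaluated = sum(scored),
      criteria = criteria
    ),
    class = "gamma_result"
  )
}

#' Global gamma-index map between two planar dose maps
#'
#' For every reference point above the low-dose threshold, the gamma index is
#' the minimum over evaluated positions of
#' `sqrt((dr/dta)^2 + (dD / (dose_percent * Dmax / 100))^2)`, with the
#' evaluated map bilinearly upsampled for sub-grid minimization: a coarse
#' lattice pass at `0.04 * dta` followed by a `0.02 * dta` refinement around
#' the best coarse node and around zero offset. The coarse search radius at
#' each point is the exact bound `dta * gamma(zero offset)`, outside which no
#' candidate can lower the minimum. Points below the threshold carry `NA` in the gamma map and are
#' excluded from the passing rate.
#'
#' @param reference Calculated (planned) `dose_plane`; supplies the global
#'   normalization maximum.
#' @param evaluated Measured `dose_plane` to compare against the reference.
#' @param criteria A [gamma_criteria()].
#' @return A `gamma_result`: `gamma` matrix over the reference grid,
#'   `passing_rate` (percent of scored points with gamma <= 1) and
#'   `n_evaluated`.
#' @export
gamma_map <- function(reference, evaluated, criteria = gamma_criteria()) {
  gamma_engine(reference, evaluated, criteria, step = 0.04 * criteria$dta,
               refine = 2)
}

#' Brute-force gamma oracle
#'
#' Reference implementation of [gamma_map()] for verification: identical
#' definition, but the evaluated-position lattice is densified to a fixed
#' 0.02 mm step. Intended for small maps (at most 101 x 101 points).
#'
#' @inheritParams gamma_map
#' @return A `gamma_result`.
#' @export
gamma_oracle <- function(reference, evaluated, criteria = gamma_criteria()) {
  if (length(reference$u) > 101 || length(reference$v) > 101) {
    stop("gamma_oracle is meant for small maps (<= 101 x 101 points)", call. = FALSE)
  }
  gamma_engine(reference, evaluated, criteria, step = 0.02)
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm, %g%% threshold: passing %.1f%% (%d points)\n",
              x$criteria$dose_percent, x$criteria$dta, x$criteria$threshold_percent,
              x$passing_rate, x$n_evaluated))
  invisible(x)
}

#' @export
tidy.gamma_result <- function(x, ...) {
  tibble::tibble(
    u = rep(x$u, times = length(x$v)),
    v = rep(x$v, each = length(x$u)),
    gamma = as.numeric(x$gamma),
    pass = as.numeric(x$gamma) <= 1 + 1e-12
  )
}

#' @export
glance.gamma_result <- function(x, ...) {
  tibble::tibble(
    passing_rate = x$passing_rate,
    n_evaluated = x$n_evaluated,
    mean_gamma = mean(x$gamma, na.rm = TRUE),
    max_gamma = max(x$gamma, na.rm = TRUE),
    dose_percent = x$criteria$dose_percent,
    dta = x$criteria$dta,
    threshold_percent = x$criteria$threshold_percent
  )
}
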