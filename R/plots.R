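#' @export
autoplot.dose_plane <- function(object, ...) {
  df <- as_tibble.dose_plane(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v, fill = .data$dose)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dose (cGy)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(object$axes[1], " [mm]"),
                  y = paste0(object$axes[2], " [mm]"),
                  title = paste(object$orientation, "dose plane")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gamma_result <- function(object, ...) {
  df <- tidy.gamma_result(object)
  ggplot2::ggplot(dplyr::filter(df, !is.na(.data$gamma)),
                  ggplot2::aes(x = .data$u, y = .data$v, fill = .data$gamma)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  midpoint = 1, name = expression(gamma)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "u [mm]", y = "v [mm]",
      title = sprintf("gamma %g%%/%g mm (%g%% threshold): %.1f%% passing",
                      object$criteria$dose_percent, object$criteria$dta,
                      object$criteria$threshold_percent, object$passing_rate)
    ) +
    ggplot2::theme_minimal()
}

#' Central-axis profile plot of one or two planar dose maps
#'
#' @param calculated A `dose_plane`.
#' @param measured Optional second `dose_plane` overlaid as points.
#' @return A ggplot with the X and Y central-axis profiles.
#' @export
plot_profiles <- function(calculated, measured = NULL) {
  prof <- function(plane, label) {
    pr <- central_profiles(plane)
    dplyr::bind_rows(
      dplyr::mutate(pr$x, axis = "X (in-plane)", source = label),
      dplyr::mutate(pr$y, axis = "Y (cross-plane)", source = label)
    )
  }
  df <- prof(calculated, "calculated")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$dose)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~axis) +
    ggplot2::labs(x = "position [mm]", y = "dose (cGy)") +
    ggplot2::theme_minimal()
  if (!is.null(measured)) {
    p <- p + ggplot2::geom_point(data = prof(measured, "measured"),
                                 colour = "goldenrod", size = 1)
  }
  p
}
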