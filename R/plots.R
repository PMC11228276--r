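#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an intensity profile
#'
#' @param object A [line_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$position_nm, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (nm)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a reconstruction as a maximum-intensity projection
#'
#' Projects the expected-value volume along the chosen axis.
#'
#' @param object A `reconstruction` or `intensity_volume`.
#' @param axis Projection axis: `"z"` (default), `"y"` or `"x"`.
#' @param ... Unused.
#' @return A ggplot raster of the projection.
#' @export
autoplot.reconstruction <- function(object, axis = c("z", "y", "x"), ...) {
  axis <- match.arg(axis)
  vol <- if (inherits(object, "reconstruction")) object$mean_volume
         else object$intensity
  g <- object$grid
  ax <- match(axis, c("x", "y", "z"))
  keep <- setdiff(1:3, ax)
  proj <- apply(vol, keep, max)
  df <- tidyr::expand_grid(b = grid_centers(g, keep[2]),
                           a = grid_centers(g, keep[1]))[c("a", "b")]
  df$intensity <- as.vector(proj)
  labs <- c("x (nm)", "y (nm)", "z (nm)")
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = labs[keep[1]], y = labs[keep[2]]) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.reconstruction
#' @export
autoplot.intensity_volume <- autoplot.reconstruction

#' Plot a scan waveform
#'
#' @param object A [scan_waveform()].
#' @param duration Time span to draw (ms); default two periods.
#' @param ... Unused.
#' @return A ggplot of focus position versus time.
#' @export
autoplot.scan_waveform <- function(object, duration = NULL, ...) {
  if (is.null(duration)) {
    per <- waveform_period(object)
    duration <- if (is.finite(per)) 2 * per else 10
  }
  t <- seq(0, duration, length.out = 512)
  df <- waveform_position(object, t)
  ggplot2::ggplot(df, ggplot2::aes(.data$t_ms, .data$z_nm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "focus z (nm)") +
    ggplot2::theme_minimal()
}

#' Plot one frame of a frame stack
#'
#' @param object A `frame_stack`.
#' @param frame 1-based frame index.
#' @param ... Unused.
#' @return A ggplot raster.
#' @export
autoplot.frame_stack <- function(object, frame = 1, ...) {
  m <- object$frames[, , frame]
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$counts <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$counts)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}

#' @export
plot.profile <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.reconstruction <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.scan_waveform <- function(x, ...) print(autoplot(x, ...))
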