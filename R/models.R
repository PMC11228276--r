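#' Point-spread-function model
#'
#' A separable 3D Gaussian approximation of the confocal PSF, parameterised by
#' its lateral and axial standard deviations.  Wavelength and numerical
#' aperture are carried as metadata only; they do not enter any computation.
#'
#' @param sigma_xy Lateral standard deviation (nm); must be positive.
#' @param sigma_z Axial standard deviation (nm); must be positive.
#' @param wavelength Emission wavelength (nm), metadata.
#' @param na Numerical aperture, metadata.
#' @return An object of class `psf_model`.
#' @examples
#' psf_model(sigma_xy = 110, sigma_z = 300)
#' @export
psf_model <- function(sigma_xy, sigma_z, wavelength = NA_real_, na = NA_real_) {
  stopifnot(is.numeric(sigma_xy), length(sigma_xy) == 1, is.finite(sigma_xy),
            is.numeric(sigma_z), length(sigma_z) == 1, is.finite(sigma_z))
  if (sigma_xy <= 0) stop("`sigma_xy` must be > 0", call. = FALSE)
  if (sigma_z <= 0) stop("`sigma_z` must be > 0", call. = FALSE)
  structure(list(sigma_xy = sigma_xy, sigma_z = sigma_z,
                 wavelength = wavelength, na = na),
            class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  cat("<psf_model> separable 3D Gaussian\n")
  cat(sprintf("  sigma_xy: %g nm (FWHM %.1f nm)\n", x$sigma_xy, 2.3548 * x$sigma_xy))
  cat(sprintf("  sigma_z:  %g nm (FWHM %.1f nm)\n", x$sigma_z, 2.3548 * x$sigma_z))
  invisible(x)
}

#' Image-intensifier model
#'
#' Each detected photon is amplified by the intensifier into a cluster of
#' camera counts: a 2D Gaussian spot of width `spot_sigma` (camera pixels)
#' whose integrated amplitude is drawn from a gamma distribution with mean
#' `gain_mean` and shape `gain_shape`.  The broad gamma law reflects the
#' wide pulse-height distribution of microchannel-plate amplification.
#'
#' @param gain_mean Mean integrated cluster amplitude (camera counts per
#'   photon); must be positive.
#' @param gain_shape Gamma shape parameter (dimensionless); must be positive.
#'   The default 2 gives a broad but zero-avoiding amplitude distribution.
#' @param spot_sigma Gaussian spot width on the camera (pixels); must be
#'   positive.
#' @return An object of class `ii_model`.
#' @examples
#' ii_model(gain_mean = 800, spot_sigma = 1)
#' @export
ii_model <- function(gain_mean, gain_shape = 2, spot_sigma = 1) {
  stopifnot(is.numeric(gain_mean), is.numeric(gain_shape), is.numeric(spot_sigma))
  if (gain_mean <= 0) stop("`gain_mean` must be > 0", call. = FALSE)
  if (gain_shape <= 0) stop("`gain_shape` must be > 0", call. = FALSE)
  if (spot_sigma <= 0) stop("`spot_sigma` must be > 0", call. = FALSE)
  structure(list(gain_mean = gain_mean, gain_shape = gain_shape,
                 spot_sigma = spot_sigma),
            class = "ii_model")
}

#' @export
print.ii_model <- function(x, ...) {
  cat(sprintf("<ii_model> gain mean %g counts/photon (gamma shape %g), spot sigma %g px\n",
              x$gain_mean, x$gain_shape, x$spot_sigma))
  invisible(x)
}

#' Camera model
#'
#' Geometry and noise model of the high-speed camera.  Coordinates are
#' continuous object-space nanometres with the origin at the field corner;
#' pixel `(i, j)` (0-based row/column) spans
#' `[j*p, (j+1)*p) x [i*p, (i+1)*p)` with `p = pixel_size`, so pixel centres
#' sit at half-pixel positions.
#'
#' @param shape Integer vector `c(rows, cols)`.
#' @param pixel_size Pixel size in object space (nm/pixel); must be positive.
#' @param frame_interval Frame interval (ms); must be positive.
#' @param read_noise_sigma Gaussian read noise (counts); must be >= 0.
#' @param offset Camera offset (counts).
#' @param hot_pixels Data frame or tibble with columns `row`, `col` (1-based)
#'   and `value` (counts added at that pixel in every frame), or `NULL`.
#' @param bit_depth Bit depth used for clipping/quantisation (default 16).
#' @return An object of class `camera_model`.
#' @examples
#' camera_model(shape = c(64, 64), pixel_size = 20, frame_interval = 1)
#' @export
camera_model <- function(shape, pixel_size, frame_interval,
                         read_noise_sigma = 0, offset = 0,
                         hot_pixels = NULL, bit_depth = 16) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2, all(shape >= 4))
  if (pixel_size <= 0) stop("`pixel_size` must be > 0", call. = FALSE)
  if (frame_interval <= 0) stop("`frame_interval` must be > 0", call. = FALSE)
  if (read_noise_sigma < 0) stop("`read_noise_sigma` must be >= 0", call. = FALSE)
  if (!is.null(hot_pixels)) {
    hot_pixels <- tibble::as_tibble(hot_pixels)
    stopifnot(all(c("row", "col", "value") %in% names(hot_pixels)))
    stopifnot(all(hot_pixels$row >= 1 & hot_pixels$row <= shape[1]),
              all(hot_pixels$col >= 1 & hot_pixels$col <= shape[2]))
  } else {
    hot_pixels <- tibble::tibble(row = integer(), col = integer(),
                                 value = numeric())
  }
  structure(list(shape = shape, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 read_noise_sigma = read_noise_sigma, offset = offset,
                 hot_pixels = hot_pixels, bit_depth = as.integer(bit_depth)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %d x %d px, %g nm/px, %g ms/frame\n",
              x$shape[1], x$shape[2], x$pixel_size, x$frame_interval))
  cat(sprintf("  offset %g, read noise %g counts, %d hot pixel(s), %d-bit\n",
              x$offset, x$read_noise_sigma, nrow(x$hot_pixels), x$bit_depth))
  invisible(x)
}
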