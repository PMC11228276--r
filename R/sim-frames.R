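#' Render camera frames from a photon list
#'
#' Applies the image-intensifier and camera model.  Each photon becomes one
#' cluster: a 2D Gaussian spot of width `ii$spot_sigma` pixels, integrated
#' over pixel areas, with integrated amplitude drawn from a gamma
#' distribution (mean `gain_mean`, shape `gain_shape`).  Frames then receive
#' the camera offset, Gaussian read noise and hot-pixel values, and are
#' clipped to `[0, 2^bit_depth - 1]` and rounded.  Photons outside the field
#' are clipped to it (counted in the attached log).
#'
#' @param photons A photon table with `x_nm`, `y_nm`, `frame`.
#' @param ii An [ii_model()].
#' @param cam A [camera_model()].
#' @param n_frames Number of frames to render; defaults to `max(frame) + 1`.
#' @param seed RNG seed.
#' @return A `frame_stack`: list with `frames` (rows x cols x n array),
#'   `pixel_size_nm`, `frame_interval_ms`, `dark` flag, and a rendering log.
#' @export
render_frames <- function(photons, ii, cam, n_frames = NULL, seed = NULL) {
  stopifnot(inherits(ii, "ii_model"), inherits(cam, "camera_model"))
  photons <- tibble::as_tibble(photons)
  if (is.null(n_frames)) {
    n_frames <- if (nrow(photons)) max(photons$frame) + 1L else 1L
  }
  n_frames <- as.integer(n_frames)
  if (!is.null(seed)) withr::local_seed(seed)
  nr <- cam$shape[1]; nc <- cam$shape[2]; p <- cam$pixel_size
  arr <- array(0, dim = c(nr, nc, n_frames))

  n_clipped <- 0L
  if (nrow(photons)) {
    # pixel-centre coordinates, 0-based: centre of pixel (i0, j0) is at
    # ((j0 + 0.5) * p, (i0 + 0.5) * p)
    px <- photons$x_nm / p - 0.5
    py <- photons$y_nm / p - 0.5
    clip <- px < 0 | px > nc - 1 | py < 0 | py > nr - 1
    n_clipped <- sum(clip)
    px <- pmin(pmax(px, 0), nc - 1)
    py <- pmin(pmax(py, 0), nr - 1)
    amp <- stats::rgamma(nrow(photons), shape = ii$gain_shape,
                         scale = ii$gain_mean / ii$gain_shape)
    r_st <- max(2L, as.integer(ceiling(4 * ii$spot_sigma)))
    off <- seq(-r_st, r_st)
    for (q in seq_len(nrow(photons))) {
      f <- photons$frame[q] + 1L
      if (f > n_frames) next
      jc <- as.integer(round(px[q])); ic <- as.integer(round(py[q]))
      js <- jc + off; is <- ic + off
      jok <- js >= 0 & js <= nc - 1; iok <- is >= 0 & is <= nr - 1
      js <- js[jok]; is <- is[iok]
      # integral of the unit Gaussian over each pixel row/column
      gx <- stats::pnorm(js + 0.5, px[q], ii$spot_sigma) -
            stats::pnorm(js - 0.5, px[q], ii$spot_sigma)
      gy <- stats::pnorm(is + 0.5, py[q], ii$spot_sigma) -
            stats::pnorm(is - 0.5, py[q], ii$spot_sigma)
      arr[is + 1L, js + 1L, f] <- arr[is + 1L, js + 1L, f] +
        amp[q] * outer(gy, gx)
    }
  }

  arr <- arr + cam$offset
  if (cam$read_noise_sigma > 0)
    arr <- arr + stats::rnorm(length(arr), sd = cam$read_noise_sigma)
  if (nrow(cam$hot_pixels)) {
    for (h in seq_len(nrow(cam$hot_pixels))) {
      arr[cam$hot_pixels$row[h], cam$hot_pixels$col[h], ] <-
        arr[cam$hot_pixels$row[h], cam$hot_pixels$col[h], ] +
        cam$hot_pixels$value[h]
    }
  }
  maxv <- 2^cam$bit_depth - 1
  arr <- round(pmin(pmax(arr, 0), maxv))

  frame_stack(arr, pixel_size_nm = p, frame_interval_ms = cam$frame_interval,
              dark = FALSE,
              log = tibble::tibble(cause = "clipped_to_field", n = n_clipped))
}

#' Simulate dark calibration frames
#'
#' Frames containing only the camera offset, read noise and hot pixels --
#' the input to [calibrate_camera()].
#'
#' @param cam A [camera_model()].
#' @param n_frames Number of frames (>= 1).
#' @param seed RNG seed.
#' @return A `frame_stack` flagged as dark.
#' @export
simulate_dark_frames <- function(cam, n_frames, seed = NULL) {
  stopifnot(inherits(cam, "camera_model"), n_frames >= 1)
  empty <- tibble::tibble(x_nm = numeric(), y_nm = numeric(), frame = integer())
  fs <- render_frames(empty, ii_model(gain_mean = 1), cam,
                      n_frames = n_frames, seed = seed)
  fs$dark <- TRUE
  fs
}

#' Construct a frame stack
#'
#' Container for time-ordered camera frames: a `rows x cols x n_frames`
#' array with pixel-size and timing metadata.
#'
#' @param frames 3D array (or a matrix for a single frame).
#' @param pixel_size_nm Pixel size in object space (nm).
#' @param frame_interval_ms Frame interval (ms).
#' @param dark Logical flag marking a dark calibration stack.
#' @param log Optional tibble of rendering/processing notes.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size_nm, frame_interval_ms,
                        dark = FALSE, log = NULL) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1))
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  structure(list(frames = frames, pixel_size_nm = pixel_size_nm,
                 frame_interval_ms = frame_interval_ms, dark = dark,
                 log = log),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frame(s) of %d x %d px, %g nm/px, %g ms/frame%s\n",
              d[3], d[1], d[2], x$pixel_size_nm, x$frame_interval_ms,
              if (isTRUE(x$dark)) " [dark]" else ""))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)
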