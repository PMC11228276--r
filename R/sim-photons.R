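#' Simulate detected photons from an emitter set
#'
#' Forward model of photon emission and confocal detection.  For every
#' camera frame (one frame per waveform plane interval) each emitter
#' produces a Poisson number of detected photons with mean
#' `brightness * frame_interval * w`, where the axial detection weight is
#' `w = exp(-(z_focus - z_emitter)^2 / (2 * sigma_z^2))` evaluated at the
#' frame's mid-exposure.  Each photon's lateral position is the emitter
#' position plus an isotropic 2D Gaussian deviate of `sigma_xy`, and its
#' emission time is uniform within the frame's exposure.
#'
#' @param emitters An [generate_emitters()] tibble (or any tibble with
#'   `x_nm`, `y_nm`, `z_nm`, `brightness`).
#' @param psf A [psf_model()].
#' @param waveform A [scan_waveform()].
#' @param duration Acquisition length (ms); must be > 0.
#' @param frame_interval Camera frame interval (ms); defaults to the
#'   waveform's plane interval (one frame per plane).
#' @param seed RNG seed; identical seeds give identical photon tables.
#' @return A tibble of class `photon_table` with columns `x_nm`, `y_nm`,
#'   `t_ms`, `frame`, `emitter` (row index in `emitters`), ordered by time.
#' @examples
#' em <- generate_emitters("point", brightness = 1)
#' wf <- scan_waveform("static")
#' ph <- simulate_photons(em, psf_model(110, 300), wf, duration = 100, seed = 1)
#' @export
simulate_photons <- function(emitters, psf, waveform, duration,
                             frame_interval = NULL, seed = NULL) {
  stopifnot(inherits(psf, "psf_model"), inherits(waveform, "scan_waveform"))
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  emitters <- tibble::as_tibble(emitters)
  if (nrow(emitters) == 0) stop("`emitters` must be nonempty", call. = FALSE)
  if (is.null(frame_interval)) frame_interval <- waveform$plane_interval
  if (!is.null(seed)) withr::local_seed(seed)
  n_frames <- as.integer(floor(duration / frame_interval))
  if (n_frames < 1) stop("`duration` shorter than one frame", call. = FALSE)
  t_mid <- (seq_len(n_frames) - 0.5) * frame_interval
  z_focus <- z_of_time(waveform, t_mid)

  parts <- vector("list", nrow(emitters))
  for (e in seq_len(nrow(emitters))) {
    b <- emitters$brightness[e]
    if (b <= 0) next
    w <- exp(-(z_focus - emitters$z_nm[e])^2 / (2 * psf$sigma_z^2))
    counts <- stats::rpois(n_frames, b * frame_interval * w)
    tot <- sum(counts)
    if (tot == 0) next
    fr <- rep.int(seq_len(n_frames) - 1L, counts)
    parts[[e]] <- tibble::tibble(
      x_nm = emitters$x_nm[e] + stats::rnorm(tot, sd = psf$sigma_xy),
      y_nm = emitters$y_nm[e] + stats::rnorm(tot, sd = psf$sigma_xy),
      t_ms = (fr + stats::runif(tot)) * frame_interval,
      frame = fr,
      emitter = e)
  }
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0) {
    out <- tibble::tibble(x_nm = numeric(), y_nm = numeric(), t_ms = numeric(),
                          frame = integer(), emitter = integer())
  }
  out <- out[order(out$t_ms), , drop = FALSE]
  attr(out, "frame_interval_ms") <- frame_interval
  attr(out, "duration_ms") <- duration
  class(out) <- c("photon_table", class(out))
  out
}
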