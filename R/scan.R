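#' Piezo z-scan waveform
#'
#' Describes the commanded z trajectory of the objective.  In `saw` mode the
#' focus ramps linearly from 0 to `n_planes * pitch` over
#' `n_planes * plane_interval` ms and then parks at 0 for `blank` ms before
#' the next sweep.  In `triangular` mode it ramps up and straight back down
#' with no blank time, so up and down sweeps alternate continuously.  In
#' `static` mode the focus stays at `z_static`.
#'
#' The number of planes per sweep is `round(z_range / pitch)`; e.g. a 5000-nm
#' range at 66.7-nm pitch gives 75 planes.
#'
#' @param mode One of `"saw"`, `"triangular"`, `"static"`.
#' @param z_range Scan range (nm); ignored for `static`.
#' @param pitch Plane spacing (nm); must be > 0.
#' @param plane_interval Time per plane (ms); one camera frame per plane.
#' @param blank Blank (fly-back) time in ms; saw mode only, must be 0 for
#'   triangular mode.
#' @param z_static Focus position for `static` mode (nm).
#' @return An object of class `scan_waveform`.
#' @examples
#' scan_waveform("triangular", z_range = 4500, pitch = 90, plane_interval = 1)
#' @export
scan_waveform <- function(mode = c("saw", "triangular", "static"),
                          z_range = NULL, pitch = NULL, plane_interval = NULL,
                          blank = 0, z_static = 0) {
  mode <- match.arg(mode)
  if (mode == "static") {
    if (is.null(plane_interval)) plane_interval <- 1
    wf <- list(mode = mode, z_range = 0, pitch = 1, plane_interval = plane_interval,
               blank = 0, n_planes = 1L, z_static = z_static)
    return(structure(wf, class = "scan_waveform"))
  }
  stopifnot(!is.null(z_range), !is.null(pitch), !is.null(plane_interval))
  if (pitch <= 0) stop("`pitch` must be > 0", call. = FALSE)
  if (plane_interval <= 0) stop("`plane_interval` must be > 0", call. = FALSE)
  if (mode == "triangular" && blank != 0)
    stop("triangular mode is operated without any blank time (`blank` must be 0)",
         call. = FALSE)
  if (blank < 0) stop("`blank` must be >= 0", call. = FALSE)
  n_planes <- as.integer(round(z_range / pitch))
  if (n_planes < 1) stop("`z_range`/`pitch` must give at least one plane", call. = FALSE)
  structure(list(mode = mode, z_range = z_range, pitch = pitch,
                 plane_interval = plane_interval, blank = blank,
                 n_planes = n_planes, z_static = 0),
            class = "scan_waveform")
}

#' @export
print.scan_waveform <- function(x, ...) {
  if (x$mode == "static") {
    cat(sprintf("<scan_waveform> static focus at %g nm\n", x$z_static))
  } else {
    cat(sprintf("<scan_waveform> %s: %g nm range, %g nm pitch (%d planes), %g ms/plane",
                x$mode, x$z_range, x$pitch, x$n_planes, x$plane_interval))
    if (x$mode == "saw") cat(sprintf(", %g ms blank", x$blank))
    cat("\n")
  }
  invisible(x)
}

# sweep (ramp) duration in ms
sweep_duration <- function(waveform) waveform$n_planes * waveform$plane_interval

# full period in ms (saw: ramp + blank; triangular: up + down)
waveform_period <- function(waveform) {
  switch(waveform$mode,
         saw = sweep_duration(waveform) + waveform$blank,
         triangular = 2 * sweep_duration(waveform),
         static = Inf)
}

#' Focus position as a function of time
#'
#' Evaluates the commanded piezo waveform.  The ramp slope is
#' `pitch / plane_interval`, so at the mid-exposure of frame `k` on an up
#' ramp the focus sits at `(k + 0.5) * pitch`.  During the saw-mode blank the
#' focus is parked at 0; use [waveform_position()] to obtain the in-blank
#' flag and sweep metadata.
#'
#' @param waveform A [scan_waveform()].
#' @param t Time(s) in ms since acquisition start; must be >= 0.
#' @return Numeric vector of focus z positions (nm).
#' @examples
#' wf <- scan_waveform("triangular", z_range = 4500, pitch = 90, plane_interval = 1)
#' z_of_time(wf, c(50, 100))  # apex, then back to 0
#' @export
z_of_time <- function(waveform, t) {
  stopifnot(inherits(waveform, "scan_waveform"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  if (waveform$mode == "static") return(rep(waveform$z_static, length(t)))
  slope <- waveform$pitch / waveform$plane_interval
  ramp <- sweep_duration(waveform)
  if (waveform$mode == "saw") {
    tp <- t %% waveform_period(waveform)
    ifelse(tp < ramp, slope * tp, 0)
  } else {
    tp <- t %% (2 * ramp)
    ifelse(tp < ramp, slope * tp, slope * (2 * ramp - tp))
  }
}

#' Focus position with sweep metadata
#'
#' Like [z_of_time()] but returns a tibble with the sweep index, sweep
#' direction and saw-blank flag for each time point.
#'
#' @inheritParams z_of_time
#' @return A tibble with columns `t_ms`, `z_nm`, `sweep`, `direction`
#'   (`"up"`, `"down"` or `"static"`) and `in_blank`.
#' @export
waveform_position <- function(waveform, t) {
  stopifnot(inherits(waveform, "scan_waveform"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  z <- z_of_time(waveform, t)
  if (waveform$mode == "static") {
    return(tibble::tibble(t_ms = t, z_nm = z, sweep = 0L,
                          direction = "static", in_blank = FALSE))
  }
  ramp <- sweep_duration(waveform)
  if (waveform$mode == "saw") {
    per <- waveform_period(waveform)
    tp <- t %% per
    tibble::tibble(t_ms = t, z_nm = z, sweep = as.integer(t %/% per),
                   direction = "up", in_blank = tp >= ramp)
  } else {
    sweep <- as.integer(t %/% ramp)
    tibble::tibble(t_ms = t, z_nm = z, sweep = sweep,
                   direction = ifelse(sweep %% 2L == 0L, "up", "down"),
                   in_blank = FALSE)
  }
}

#' Group an acquisition into reconstruction windows
#'
#' Builds the time windows over which photons are pooled for one
#' reconstructed volume.  `consecutive` gives one window per sweep (saw) or
#' per half-period (triangular).  The moving-average patterns are
#' triangular-only: `pattern1` pools one up-down (or down-up) pair of sweeps
#' (a 2-sweep window) stepped by one sweep; `pattern2` pools two pairs
#' (a 4-sweep window), also stepped by one sweep.  The display interval is
#' one sweep duration in every case.
#'
#' @param waveform A [scan_waveform()] (saw or triangular).
#' @param duration Acquisition length (ms).
#' @param pattern One of `"consecutive"`, `"pattern1"`, `"pattern2"`.
#' @return A tibble of class `volume_plan` with columns `window`,
#'   `t_start_ms`, `t_end_ms`, `n_sweeps`, `direction`, `pattern`,
#'   `frame_first`, `frame_last`, and attribute `display_interval_ms`.
#' @examples
#' wf <- scan_waveform("triangular", z_range = 4500, pitch = 90, plane_interval = 1)
#' plan_volumes(wf, duration = 1000, pattern = "pattern1")
#' @export
plan_volumes <- function(waveform, duration,
                         pattern = c("consecutive", "pattern1", "pattern2")) {
  stopifnot(inherits(waveform, "scan_waveform"))
  pattern <- match.arg(pattern)
  if (waveform$mode == "static")
    stop("volume planning requires a scanning waveform", call. = FALSE)
  if (pattern != "consecutive" && waveform$mode != "triangular")
    stop("moving-average patterns are triangular-only", call. = FALSE)
  ramp <- sweep_duration(waveform)
  dt <- waveform$plane_interval
  if (waveform$mode == "saw") {
    per <- waveform_period(waveform)
    n <- floor(duration / per)
    if (duration %% per >= ramp) n <- n + 1  # a final ramp without full blank
    if (n < 1) stop("`duration` must cover at least one full sweep", call. = FALSE)
    starts <- (seq_len(n) - 1) * per
    plan <- tibble::tibble(window = seq_len(n), t_start_ms = starts,
                           t_end_ms = starts + ramp, n_sweeps = 1L,
                           direction = "up", pattern = pattern)
  } else {
    n_sweeps_total <- floor(duration / ramp)
    need <- switch(pattern, consecutive = 1L, pattern1 = 2L, pattern2 = 4L)
    if (n_sweeps_total < need)
      stop(sprintf("`duration` covers %d sweep(s); pattern needs at least %d",
                   n_sweeps_total, need), call. = FALSE)
    n <- n_sweeps_total - need + 1L
    starts <- (seq_len(n) - 1) * ramp
    dirs <- if (need == 1L) {
      ifelse((seq_len(n) - 1) %% 2 == 0, "up", "down")
    } else {
      rep("updown", n)
    }
    plan <- tibble::tibble(window = seq_len(n), t_start_ms = starts,
                           t_end_ms = starts + need * ramp, n_sweeps = need,
                           direction = dirs, pattern = pattern)
  }
  plan$frame_first <- as.integer(plan$t_start_ms %/% dt)
  plan$frame_last <- as.integer(ceiling(plan$t_end_ms / dt)) - 1L
  attr(plan, "display_interval_ms") <- ramp
  attr(plan, "waveform") <- waveform
  class(plan) <- c("volume_plan", class(plan))
  plan
}

#' Assign z coordinates to detected photons
#'
#' Looks up the focus position for every event and adds it as `z_nm`.  By
#' default the waveform is evaluated at the mid-exposure of the event's
#' frame (`timing = "frame"`), which is all a frame-integrating camera can
#' know.  `timing = "exact"` evaluates at the event's own timestamp and is
#' appropriate for simulated photon tables that carry continuous emission
#' times.  Saw-mode events whose evaluation time falls in the blank are
#' dropped and counted in the attached log.
#'
#' @param photons A photon table (tibble) with columns `t_ms` and `frame`.
#' @param waveform A [scan_waveform()].
#' @param timing `"frame"` (mid-exposure of the frame) or `"exact"`.
#' @return The photon table with a `z_nm` column; dropped-event counts are in
#'   `attr(, "log")`.
#' @export
assign_z <- function(photons, waveform, timing = c("frame", "exact")) {
  stopifnot(inherits(waveform, "scan_waveform"))
  timing <- match.arg(timing)
  photons <- tibble::as_tibble(photons)
  t_eval <- if (timing == "frame") {
    (photons$frame + 0.5) * waveform$plane_interval
  } else {
    photons$t_ms
  }
  pos <- waveform_position(waveform, t_eval)
  out <- photons
  out$z_nm <- pos$z_nm
  keep <- !pos$in_blank
  n_drop <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  attr(out, "log") <- tibble::tibble(cause = "in_blank", n = n_drop)
  out
}
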