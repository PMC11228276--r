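#' Calibrate camera background from a dark stack
#'
#' Estimates the per-pixel offset (mean) and noise sigma (standard
#' deviation) from dark frames, and flags hot pixels: pixels whose mean
#' exceeds the global median offset by more than ten times the median sigma.
#' Hot pixels are excluded from event detection.
#'
#' @param dark A `frame_stack` flagged as dark.
#' @param k Detection threshold factor (default 5): an event centre must
#'   exceed the local offset by at least `k` local sigma.  At this setting
#'   the Gaussian tail keeps false events on a full-frame, kHz acquisition
#'   far below one per second.
#' @return An object of class `camera_calibration` with `offset` and `sigma`
#'   matrices, logical `hot` mask and `k`.
#' @export
calibrate_camera <- function(dark, k = 5) {
  stopifnot(inherits(dark, "frame_stack"))
  if (!isTRUE(dark$dark)) stop("stack is not flagged dark", call. = FALSE)
  d <- dim(dark$frames)
  if (d[3] < 2) stop("need at least 2 dark frames", call. = FALSE)
  n <- d[3]
  offset <- rowMeans(dark$frames, dims = 2)
  # per-pixel sd without materialising huge temporaries
  ss <- rowSums(dark$frames^2, dims = 2)
  sigma <- sqrt(pmax((ss - n * offset^2) / (n - 1), 0))
  hot <- offset > stats::median(offset) + 10 * stats::median(sigma)
  structure(list(offset = offset, sigma = sigma, hot = hot, k = k,
                 n_frames = n, pixel_size_nm = dark$pixel_size_nm),
            class = "camera_calibration")
}

#' @export
print.camera_calibration <- function(x, ...) {
  cat(sprintf("<camera_calibration> %d x %d px from %d dark frames, k = %g\n",
              nrow(x$offset), ncol(x$offset), x$n_frames, x$k))
  cat(sprintf("  median offset %.2f, median sigma %.3f, %d hot pixel(s)\n",
              stats::median(x$offset), stats::median(x$sigma), sum(x$hot)))
  invisible(x)
}

#' Cluster admission criteria
#'
#' The shape test that separates single-photon clusters from residual camera
#' noise: all eight offset-subtracted neighbour/centre intensity ratios of a
#' candidate local maximum must fall within `[ratio_low, ratio_high]`
#' (negatives clamped to zero before the ratio).  Use
#' [calibrate_ratio_band()] to derive the band for a given intensifier spot
#' width.
#'
#' @param ratio_low,ratio_high Admissible neighbour/centre ratio range;
#'   `0 <= ratio_low < ratio_high <= 1`.
#' @param min_amplitude Minimum offset-subtracted centre amplitude (counts).
#' @param isolation If `TRUE` (default), candidate pairs closer than 2 px
#'   are both rejected (overlapping clusters are not demixed).
#' @return An object of class `cluster_criteria`.
#' @export
cluster_criteria <- function(ratio_low = 0.02, ratio_high = 0.85,
                             min_amplitude = 0, isolation = TRUE) {
  if (!(ratio_low >= 0 && ratio_low < ratio_high && ratio_high <= 1))
    stop("need 0 <= ratio_low < ratio_high <= 1", call. = FALSE)
  structure(list(ratio_low = ratio_low, ratio_high = ratio_high,
                 min_amplitude = min_amplitude, isolation = isolation),
            class = "cluster_criteria")
}

#' Calibrate the neighbour/centre ratio band
#'
#' Simulates noiseless single-photon clusters at uniform sub-pixel offsets
#' for the given intensifier spot width and takes the
#' `[0.5, 99.5]` percentile envelope of the per-cluster minimum and maximum
#' neighbour/centre ratios.  This replaces a hand-set "certain range" with a
#' configuration-derived one.
#'
#' @param spot_sigma Intensifier spot width (pixels).
#' @param n Number of simulated clusters.
#' @param probs Two percentiles for the envelope.
#' @param seed RNG seed.
#' @param ... Passed to [cluster_criteria()] (e.g. `min_amplitude`).
#' @return A [cluster_criteria()] with the calibrated band.
#' @export
calibrate_ratio_band <- function(spot_sigma, n = 10000,
                                 probs = c(0.005, 0.995), seed = 1, ...) {
  if (!is.null(seed)) withr::local_seed(seed)
  dx <- stats::runif(n, -0.5, 0.5)
  dy <- stats::runif(n, -0.5, 0.5)
  lo <- hi <- numeric(n)
  for (q in seq_len(n)) {
    patch <- spot_patch(dx[q], dy[q], spot_sigma, half = 1L)
    r <- patch[-5] / patch[5]
    lo[q] <- min(r); hi[q] <- max(r)
  }
  band <- c(stats::quantile(lo, probs[1]), stats::quantile(hi, probs[2]))
  cluster_criteria(ratio_low = max(0, unname(band[1])),
                   ratio_high = min(1, unname(band[2])), ...)
}

# pixel-integrated Gaussian spot on a (2*half+1)^2 patch, centre pixel at
# (0,0) and true centre at (dx, dy) in pixel units
spot_patch <- function(dx, dy, spot_sigma, half = 1L, amplitude = 1) {
  off <- seq(-half, half)
  gx <- stats::pnorm(off + 0.5, dx, spot_sigma) -
        stats::pnorm(off - 0.5, dx, spot_sigma)
  gy <- stats::pnorm(off + 0.5, dy, spot_sigma) -
        stats::pnorm(off - 0.5, dy, spot_sigma)
  amplitude * outer(gy, gx)
}

#' Detect single-photon candidate events in one frame
#'
#' A pixel is a candidate iff it is (i) a strict local maximum over its 3x3
#' neighbourhood (plateau ties broken deterministically: the
#' lexicographically smallest pixel wins); (ii) its offset-subtracted value
#' is at least `max(min_amplitude, k * sigma)` at that pixel; (iii) all
#' eight offset-subtracted neighbour/centre ratios (negatives clamped to 0)
#' lie within the criteria band; and (iv) with isolation on, no other
#' surviving candidate centre lies within 2 px (both are dropped and
#' logged).  Hot pixels are never candidates and the 1-px border ring is
#' excluded.
#'
#' @param frame Numeric matrix (one camera frame).
#' @param calib A [calibrate_camera()] result.
#' @param criteria A [cluster_criteria()].
#' @return A tibble with 1-based `row`, `col`, the offset-subtracted centre
#'   `amplitude`, and a rejection log in `attr(, "log")`.
#' @export
detect_events <- function(frame, calib, criteria = cluster_criteria()) {
  stopifnot(is.matrix(frame), inherits(calib, "camera_calibration"))
  if (!all(dim(frame) == dim(calib$offset)))
    stop("frame/calibration shape mismatch", call. = FALSE)
  sub <- frame - calib$offset
  nr <- nrow(sub); nc <- ncol(sub)
  core_i <- 2:(nr - 1); core_j <- 2:(nc - 1)
  centre <- sub[core_i, core_j]
  is_max <- matrix(TRUE, nr - 2, nc - 2)
  ratio_ok <- matrix(TRUE, nr - 2, nc - 2)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- sub[core_i + di, core_j + dj]
    # strict maximum; on exact ties the lexicographically smaller (col-major
    # earlier) pixel wins
    later <- dj > 0 || (dj == 0 && di > 0)
    is_max <- is_max & (if (later) centre >= nb else centre > nb)
    r <- pmax(nb, 0) / centre
    ratio_ok <- ratio_ok & r >= criteria$ratio_low & r <= criteria$ratio_high
  }
  thr <- pmax(criteria$min_amplitude, calib$k * calib$sigma[core_i, core_j])
  ok <- is_max & centre > 0 & centre >= thr
  n_ratio_rej <- sum(ok & !ratio_ok)
  ok <- ok & ratio_ok & !calib$hot[core_i, core_j]
  idx <- which(ok, arr.ind = TRUE)
  cand <- tibble::tibble(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
                         amplitude = centre[ok])
  n_iso_rej <- 0L
  if (criteria$isolation && nrow(cand) > 1) {
    d2 <- outer(cand$row, cand$row, "-")^2 + outer(cand$col, cand$col, "-")^2
    close <- (d2 <= 4) & upper.tri(d2)
    drop <- unique(c(row(d2)[close], col(d2)[close]))
    n_iso_rej <- length(drop)
    if (n_iso_rej) cand <- cand[-drop, , drop = FALSE]
  }
  attr(cand, "log") <- tibble::tibble(
    cause = c("ratio_band", "isolation"),
    n = c(n_ratio_rej, n_iso_rej))
  cand
}

#' Sub-pixel localization of a photon cluster
#'
#' Determines the sub-pixel offset of a cluster from its offset-subtracted
#' 3x3 (or 5x5) patch.  `method = "cog"` returns the intensity-weighted
#' centre of gravity (negatives clamped to zero).  `method = "gauss"`
#' (default) least-squares fits a pixel-integrated 2D Gaussian with fixed
#' width `spot_sigma` and free position and amplitude, started from the
#' centre of gravity.  Offsets are confined to `[-1.5, 1.5]` px.
#'
#' @param patch Square numeric matrix of odd size, offset-subtracted, with
#'   the candidate pixel at the centre; the centre value must be positive.
#' @param method `"gauss"` or `"cog"`.
#' @param spot_sigma Fixed Gaussian width for the fit (pixels).
#' @return A list with `dx`, `dy` (px, x = column direction, y = row
#'   direction), `amplitude` (integrated counts) and `residual` (sum of
#'   squared fit errors normalised by the squared patch norm; `NA` for cog).
#' @export
localize_event <- function(patch, method = c("gauss", "cog"), spot_sigma = 1) {
  method <- match.arg(method)
  stopifnot(is.matrix(patch), nrow(patch) == ncol(patch), nrow(patch) %% 2 == 1)
  half <- (nrow(patch) - 1L) %/% 2L
  c0 <- half + 1L
  if (all(patch == 0)) stop("all-zero patch", call. = FALSE)
  if (patch[c0, c0] <= 0) stop("centre value must be positive", call. = FALSE)
  w <- pmax(patch, 0)
  off <- seq(-half, half)
  dx <- sum(t(w) * off) / sum(w)   # column direction
  dy <- sum(w * off) / sum(w)      # row direction
  if (method == "cog") {
    return(list(dx = clamp(dx, 1.5), dy = clamp(dy, 1.5),
                amplitude = sum(w), residual = NA_real_))
  }
  sse <- function(par) {
    g <- spot_patch(par[1], par[2], spot_sigma, half = half)
    a <- sum(patch * g) / sum(g * g)
    sum((patch - a * g)^2)
  }
  fit <- stats::optim(c(clamp(dx, 1.4), clamp(dy, 1.4)), sse,
                      method = "L-BFGS-B", lower = -1.5, upper = 1.5)
  g <- spot_patch(fit$par[1], fit$par[2], spot_sigma, half = half)
  a <- sum(patch * g) / sum(g * g)
  list(dx = fit$par[1], dy = fit$par[2], amplitude = a,
       residual = fit$value / sum(patch^2))
}

clamp <- function(x, lim) pmin(pmax(x, -lim), lim)

# model evaluation for a batch of 3x3 patches: given offset vectors (dx, dy),
# returns the unit-amplitude pixel-integrated Gaussian as an n x 9 matrix
# (column-major patch order) plus the per-event LS amplitude and SSE
batch_model <- function(P, dx, dy, spot_sigma) {
  gx <- lapply(-1:1, function(o)
    stats::pnorm(o + 0.5, dx, spot_sigma) - stats::pnorm(o - 0.5, dx, spot_sigma))
  gy <- lapply(-1:1, function(o)
    stats::pnorm(o + 0.5, dy, spot_sigma) - stats::pnorm(o - 0.5, dy, spot_sigma))
  G <- matrix(0, length(dx), 9L)
  k <- 0L
  for (j in 1:3) for (i in 1:3) {  # column-major: row index fastest
    k <- k + 1L
    G[, k] <- gy[[i]] * gx[[j]]
  }
  a <- rowSums(P * G) / rowSums(G * G)
  r <- P - a * G
  list(G = G, amplitude = a, sse = rowSums(r * r))
}

# vectorized fixed-sigma Gaussian localization of many 3x3 patches at once:
# damped Gauss-Newton on (dx, dy) with the amplitude profiled out, started
# from the centre of gravity; same objective as localize_event(method="gauss")
localize_batch <- function(P, spot_sigma, n_iter = 24, h = 1e-4) {
  w <- pmax(P, 0)
  tot <- rowSums(w)
  off <- rep(c(-1, 0, 1), each = 3)   # column offsets, column-major order
  ofr <- rep(c(-1, 0, 1), times = 3)  # row offsets
  dx <- clamp(colSums(t(w) * rep(c(-1, 0, 1), each = 3)) / tot, 1.4)
  dy <- clamp(colSums(t(w) * rep(c(-1, 0, 1), times = 3)) / tot, 1.4)
  cur <- batch_model(P, dx, dy, spot_sigma)
  for (it in seq_len(n_iter)) {
    sx <- batch_model(P, dx + h, dy, spot_sigma)
    sy <- batch_model(P, dx, dy + h, spot_sigma)
    gx <- (sx$sse - cur$sse) / h
    gy <- (sy$sse - cur$sse) / h
    # diagonal curvature estimate from a symmetric second difference
    mx <- batch_model(P, dx - h, dy, spot_sigma)
    my <- batch_model(P, dx, dy - h, spot_sigma)
    hx <- pmax((sx$sse - 2 * cur$sse + mx$sse) / h^2, 1e-8)
    hy <- pmax((sy$sse - 2 * cur$sse + my$sse) / h^2, 1e-8)
    ndx <- clamp(dx - gx / hx, 1.5)
    ndy <- clamp(dy - gy / hy, 1.5)
    nxt <- batch_model(P, ndx, ndy, spot_sigma)
    worse <- nxt$sse > cur$sse
    if (any(worse)) {  # halve the step where the full step overshoots
      ndx[worse] <- (dx[worse] + ndx[worse]) / 2
      ndy[worse] <- (dy[worse] + ndy[worse]) / 2
      nxt2 <- batch_model(P, ndx, ndy, spot_sigma)
      still <- nxt2$sse > cur$sse
      ndx[still] <- dx[still]; ndy[still] <- dy[still]
      nxt <- batch_model(P, ndx, ndy, spot_sigma)
    }
    moved <- max(abs(ndx - dx), abs(ndy - dy))
    dx <- ndx; dy <- ndy; cur <- nxt
    if (moved < 1e-6) break
  }
  list(dx = dx, dy = dy, amplitude = cur$amplitude,
       residual = cur$sse / rowSums(P * P))
}

#' Count single photons over a frame stack
#'
#' Runs [detect_events()] and [localize_event()] on every frame and
#' assembles the photon table: positions in nm, time at the frame
#' mid-exposure, cluster amplitude and fit residual.  The attached log
#' reports events per frame and rejection counts by cause.
#'
#' @param frames A `frame_stack`.
#' @param calib A [calibrate_camera()] result (same shape).
#' @param criteria A [cluster_criteria()].
#' @param method Localization method, `"gauss"` (default) or `"cog"`.
#' @param spot_sigma Fixed Gaussian width for the fit (pixels).
#' @param channel Channel label stored in the table.
#' @return A tibble of class `photon_table` with columns `x_nm`, `y_nm`,
#'   `t_ms`, `frame`, `amplitude`, `residual`, `channel`; summary log in
#'   `attr(, "log")`.
#' @export
count_frames <- function(frames, calib, criteria = cluster_criteria(),
                         method = c("gauss", "cog"), spot_sigma = 1,
                         channel = "ch1") {
  stopifnot(inherits(frames, "frame_stack"))
  method <- match.arg(method)
  d <- dim(frames$frames)
  if (!all(d[1:2] == dim(calib$offset)))
    stop("frame/calibration shape mismatch", call. = FALSE)
  p <- frames$pixel_size_nm
  dt <- frames$frame_interval_ms
  parts <- vector("list", d[3])
  patches <- vector("list", d[3])
  n_ratio <- 0L; n_iso <- 0L
  for (f in seq_len(d[3])) {
    fr <- frames$frames[, , f]
    cand <- detect_events(fr, calib, criteria)
    lg <- attr(cand, "log")
    n_ratio <- n_ratio + lg$n[lg$cause == "ratio_band"]
    n_iso <- n_iso + lg$n[lg$cause == "isolation"]
    if (!nrow(cand)) next
    sub <- fr - calib$offset
    P <- matrix(0, nrow(cand), 9L)
    for (q in seq_len(nrow(cand))) {
      i <- cand$row[q]; j <- cand$col[q]
      P[q, ] <- sub[(i - 1):(i + 1), (j - 1):(j + 1)]
    }
    patches[[f]] <- P
    parts[[f]] <- tibble::tibble(row = cand$row, col = cand$col,
                                 frame = f - 1L)
  }
  out <- dplyr::bind_rows(parts)
  if (nrow(out)) {
    P <- do.call(rbind, patches)
    loc <- if (method == "gauss") {
      localize_batch(P, spot_sigma)
    } else {
      w <- pmax(P, 0)
      tot <- rowSums(w)
      list(dx = clamp(colSums(t(w) * rep(c(-1, 0, 1), each = 3)) / tot, 1.5),
           dy = clamp(colSums(t(w) * rep(c(-1, 0, 1), times = 3)) / tot, 1.5),
           amplitude = tot, residual = rep(NA_real_, nrow(P)))
    }
    out <- tibble::tibble(
      x_nm = (out$col - 1 + 0.5 + loc$dx) * p,
      y_nm = (out$row - 1 + 0.5 + loc$dy) * p,
      t_ms = (out$frame + 0.5) * dt,
      frame = out$frame,
      amplitude = loc$amplitude,
      residual = loc$residual)
  }
  if (nrow(out) == 0) {
    out <- tibble::tibble(x_nm = numeric(), y_nm = numeric(), t_ms = numeric(),
                          frame = integer(), amplitude = numeric(),
                          residual = numeric())
  }
  out$channel <- rep_len(channel, nrow(out))
  attr(out, "frame_interval_ms") <- dt
  attr(out, "log") <- tibble::tibble(
    cause = c("detected", "rejected_ratio_band", "rejected_isolation"),
    n = c(nrow(out), n_ratio, n_iso))
  class(out) <- c("photon_table", class(out))
  out
}
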