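# Shared fixture builders; everything is generated in code at test time.

tiny_camera <- function(rows = 32, cols = 32, read_noise = 0, offset = 0,
                        hot = NULL, pixel_size = 20) {
  camera_model(shape = c(rows, cols), pixel_size = pixel_size,
               frame_interval = 1, read_noise_sigma = read_noise,
               offset = offset, hot_pixels = hot)
}

tiny_ii <- function(gain_mean = 800, gain_shape = 2, spot_sigma = 1) {
  ii_model(gain_mean = gain_mean, gain_shape = gain_shape,
           spot_sigma = spot_sigma)
}

default_psf <- function() psf_model(sigma_xy = 110, sigma_z = 300)

# a photon table with explicit coordinates (z optional)
manual_photons <- function(x, y, t, frame = floor(t), z = NULL) {
  out <- tibble::tibble(x_nm = x, y_nm = y, t_ms = t, frame = as.integer(frame))
  if (!is.null(z)) out$z_nm <- z
  class(out) <- c("photon_table", class(out))
  out
}

# brute-force candidate scan used as the detection oracle: literal
# re-statement of the acceptance rules, checked pixel by pixel
oracle_detect <- function(frame, offset, sigma, k, ratio_low, ratio_high,
                          min_amplitude = 0) {
  sub <- frame - offset
  nr <- nrow(sub); nc <- ncol(sub)
  hits <- NULL
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    c0 <- sub[i, j]
    if (c0 <= 0) next
    if (c0 < max(min_amplitude, k * sigma[i, j])) next
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- sub[i + di, j + dj]
      later <- dj > 0 || (dj == 0 && di > 0)
      if (!(if (later) c0 >= nb else c0 > nb)) ok <- FALSE
      r <- max(nb, 0) / c0
      if (r < ratio_low || r > ratio_high) ok <- FALSE
    }
    if (ok) hits <- rbind(hits, c(i, j))
  }
  hits
}

# dense grid-search least-squares localization oracle (independent of the
# package's optimiser)
oracle_localize <- function(patch, spot_sigma = 1, step = 0.005, lim = 0.6) {
  offs <- seq(-lim, lim, by = step)
  best <- c(NA, NA); best_sse <- Inf
  half <- (nrow(patch) - 1L) %/% 2L
  px <- seq(-half, half)
  for (dx in offs) for (dy in offs) {
    gx <- pnorm(px + 0.5, dx, spot_sigma) - pnorm(px - 0.5, dx, spot_sigma)
    gy <- pnorm(px + 0.5, dy, spot_sigma) - pnorm(px - 0.5, dy, spot_sigma)
    g <- outer(gy, gx)
    a <- sum(patch * g) / sum(g * g)
    sse <- sum((patch - a * g)^2)
    if (sse < best_sse) { best_sse <- sse; best <- c(dx, dy) }
  }
  list(dx = best[1], dy = best[2], sse = best_sse)
}

# noiseless rendered spot patch at a sub-pixel offset (amplitude in counts)
render_patch <- function(dx, dy, spot_sigma = 1, amplitude = 1000, half = 1L) {
  off <- seq(-half, half)
  gx <- pnorm(off + 0.5, dx, spot_sigma) - pnorm(off - 0.5, dx, spot_sigma)
  gy <- pnorm(off + 0.5, dy, spot_sigma) - pnorm(off - 0.5, dy, spot_sigma)
  amplitude * outer(gy, gx)
}

# independent box-constrained quasi-Newton maximizer of the Poisson
# likelihood for the same column-normalized separable forward model; used as
# the oracle for the Richardson-Lucy route
oracle_poisson_mle <- function(counts, Ax, Ay, Az, maxit = 5000) {
  A <- kronecker(Az, kronecker(Ay, Ax))  # maps vec(object) to vec(data)
  d <- as.vector(counts)
  n_obj <- ncol(A)
  total <- sum(d)
  nll <- function(f) {
    m <- pmax(A %*% f, 1e-300)
    -(sum(d * log(m)) - sum(m))
  }
  gr <- function(f) {
    m <- pmax(A %*% f, 1e-300)
    -(as.vector(crossprod(A, d / m)) - 1)
  }
  fit <- stats::optim(rep(total / n_obj, n_obj), nll, gr,
                      method = "L-BFGS-B", lower = 0,
                      control = list(maxit = maxit, factr = 10))
  list(f = fit$par, loglik = -fit$value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
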