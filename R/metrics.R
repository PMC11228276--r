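#' Sample an intensity profile along a line segment
#'
#' Trilinear interpolation of a volume along the segment from `start` to
#' `end`, sampled at steps no larger than half the smallest non-slab voxel
#' size, and averaged across the perpendicular `width` (nm).
#'
#' @param volume An `intensity_volume`, `reconstruction` (its mean volume is
#'   used), `count_volume`, or a bare array (then `grid` is required).
#' @param start,end Length-3 numeric endpoints (nm).
#' @param width Averaging width perpendicular to the line (nm, default 0).
#' @param grid A [voxel_grid()] when `volume` is a bare array.
#' @param step Sampling step (nm); default `min(voxel)/2` over non-slab axes.
#' @param n_width Number of perpendicular samples across the width.
#' @return A tibble of class `profile` with columns `position_nm` (distance
#'   along the segment) and `intensity`.
#' @export
line_profile <- function(volume, start, end, width = 0, grid = NULL,
                         step = NULL, n_width = 5) {
  if (inherits(volume, "reconstruction")) {
    grid <- volume$grid; vol <- volume$mean_volume
  } else if (inherits(volume, "intensity_volume")) {
    grid <- volume$grid; vol <- volume$intensity
  } else if (inherits(volume, "count_volume")) {
    grid <- volume$grid; vol <- volume$counts
  } else {
    stopifnot(is.array(volume), !is.null(grid))
    vol <- volume
  }
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(length(start) == 3, length(end) == 3)
  d <- end - start
  len <- sqrt(sum(d^2))
  if (len == 0) stop("zero-length segment", call. = FALSE)
  u <- d / len
  if (is.null(step)) {
    vx <- grid$voxel_size[grid$shape > 1]
    step <- if (length(vx)) min(vx) / 2 else min(grid$voxel_size) / 2
  }
  pos <- seq(0, len, by = step)
  # two unit vectors perpendicular to the line for width averaging
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- ref - sum(ref * u) * u; p1 <- p1 / sqrt(sum(p1^2))
  p2 <- c(u[2] * p1[3] - u[3] * p1[2], u[3] * p1[1] - u[1] * p1[3],
          u[1] * p1[2] - u[2] * p1[1])
  offs <- if (width > 0) seq(-width / 2, width / 2, length.out = n_width) else 0
  acc <- numeric(length(pos))
  n_avg <- 0L
  for (o1 in offs) for (o2 in offs) {
    pts <- cbind(start[1] + pos * u[1] + o1 * p1[1] + o2 * p2[1],
                 start[2] + pos * u[2] + o1 * p1[2] + o2 * p2[2],
                 start[3] + pos * u[3] + o1 * p1[3] + o2 * p2[3])
    acc <- acc + trilinear(vol, grid, pts)
    n_avg <- n_avg + 1L
  }
  out <- tibble::tibble(position_nm = pos, intensity = acc / n_avg)
  attr(out, "sampling_width_nm") <- width
  class(out) <- c("profile", class(out))
  out
}

# trilinear interpolation at points (n x 3 matrix of nm coords); outside the
# grid the volume is taken as 0
trilinear <- function(vol, grid, pts) {
  n <- nrow(pts)
  res <- numeric(n)
  cc <- list(grid_centers(grid, 1), grid_centers(grid, 2), grid_centers(grid, 3))
  f <- matrix(0, n, 3); i0 <- matrix(0L, n, 3)
  for (a in 1:3) {
    if (grid$shape[a] == 1L) { i0[, a] <- 1L; f[, a] <- 0; next }
    t <- (pts[, a] - cc[[a]][1]) / grid$voxel_size[a]
    i <- floor(t)
    f[, a] <- t - i
    i0[, a] <- as.integer(i) + 1L
  }
  sh <- grid$shape
  for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
    ix <- i0[, 1] + if (sh[1] > 1) bx else 0L
    iy <- i0[, 2] + if (sh[2] > 1) by else 0L
    iz <- i0[, 3] + if (sh[3] > 1) bz else 0L
    wx <- if (sh[1] > 1) (if (bx) f[, 1] else 1 - f[, 1]) else if (bx) 0 else 1
    wy <- if (sh[2] > 1) (if (by) f[, 2] else 1 - f[, 2]) else if (by) 0 else 1
    wz <- if (sh[3] > 1) (if (bz) f[, 3] else 1 - f[, 3]) else if (bz) 0 else 1
    ok <- ix >= 1 & ix <= sh[1] & iy >= 1 & iy <= sh[2] & iz >= 1 & iz <= sh[3]
    w <- wx * wy * wz
    if (any(ok & w > 0)) {
      lin <- ix[ok] + sh[1] * (iy[ok] - 1L + sh[2] * (iz[ok] - 1L))
      res[ok] <- res[ok] + (w * as.numeric(ok))[ok] * vol[lin]
    }
  }
  res
}

#' Two-peak separation by the Rayleigh dip criterion
#'
#' Finds the two highest local maxima of a profile and tests whether the
#' minimum between them falls below `dip_fraction` times the lower peak
#' (the Rayleigh-style resolvability criterion; two ideal Airy peaks at the
#' Rayleigh distance dip to ~0.735 of the peak).  Peak positions are
#' refined by parabolic interpolation through each maximum and its two
#' neighbours.
#'
#' @param profile A [line_profile()] tibble (>= 5 samples).
#' @param dip_fraction Dip threshold as a fraction of the lower peak.
#' @return A list with `resolved` (logical), `separation` (nm, `NA` when
#'   unresolved or fewer than two maxima), `dip_ratio`, and a `peaks`
#'   tibble.
#' @export
peak_separation <- function(profile, dip_fraction = 0.735) {
  stopifnot(is.data.frame(profile), nrow(profile) >= 5)
  x <- profile$position_nm; y <- profile$intensity
  n <- length(y)
  loc <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(loc) < 2)
    return(list(resolved = FALSE, separation = NA_real_, dip_ratio = NA_real_,
                peaks = tibble::tibble(position_nm = x[loc], intensity = y[loc])))
  top <- loc[order(-y[loc])][1:2]
  i <- min(top); j <- max(top)
  dip <- min(y[i:j])
  lower_peak <- min(y[i], y[j])
  dip_ratio <- dip / lower_peak
  refine <- function(k) {
    a <- y[k - 1]; b <- y[k]; cc <- y[k + 1]
    den <- a - 2 * b + cc
    if (den == 0) return(x[k])
    x[k] + 0.5 * (a - cc) / den * (x[k + 1] - x[k])
  }
  sep <- abs(refine(j) - refine(i))
  resolved <- dip_ratio <= dip_fraction
  list(resolved = resolved,
       separation = if (resolved) sep else NA_real_,
       dip_ratio = dip_ratio,
       peaks = tibble::tibble(position_nm = c(refine(i), refine(j)),
                              intensity = y[c(i, j)]))
}

#' Full width at half maximum of a profile
#'
#' Linear-interpolated width of the (unique) global maximum at half of the
#' baseline-subtracted peak height; the baseline is the profile minimum.
#' Scaling the intensities leaves the result unchanged.
#'
#' @param profile A [line_profile()] tibble.
#' @return Width in nm.
#' @export
fwhm <- function(profile) {
  x <- profile$position_nm; y <- profile$intensity
  base <- min(y)
  y <- y - base
  k <- which.max(y)
  half <- y[k] / 2
  left <- which(y[1:k] < half)
  right <- which(y[k:length(y)] < half) + k - 1L
  if (!length(left) || !length(right))
    stop("profile never falls below half maximum on one side", call. = FALSE)
  l <- max(left)
  r <- min(right)
  xl <- x[l] + (half - y[l]) / (y[l + 1] - y[l]) * (x[l + 1] - x[l])
  xr <- x[r - 1] + (y[r - 1] - half) / (y[r - 1] - y[r]) * (x[r] - x[r - 1])
  xr - xl
}

#' Estimate the PSF from bead acquisitions
#'
#' Pools the per-bead sample standard deviations of photon coordinates
#' about the known bead centres and corrects for the finite bead size by
#' subtracting the uniform-sphere second moment (`radius^2 / 5` per axis)
#' in quadrature.
#'
#' @param photons Photon table with `x_nm`, `y_nm` and (optionally) `z_nm`,
#'   and an `emitter` or `bead` column mapping photons to beads; a single
#'   bead may omit it.
#' @param bead_positions Tibble/data frame with `x_nm`, `y_nm`, `z_nm` (one
#'   row per bead).
#' @param bead_diameter Bead diameter (nm); 0 for point-like sources.
#' @param min_photons Minimum pooled photon count considered reliable.
#' @return A [psf_model()] estimate.  When photons carry no usable `z_nm`
#'   the axial width cannot be estimated and `sigma_z` falls back to the
#'   lateral estimate.
#' @export
measure_psf <- function(photons, bead_positions, bead_diameter = 0,
                        min_photons = 500) {
  photons <- tibble::as_tibble(photons)
  bead_positions <- tibble::as_tibble(bead_positions)
  if (nrow(bead_positions) < 1) stop("need at least one bead", call. = FALSE)
  id <- if ("bead" %in% names(photons)) photons$bead
        else if ("emitter" %in% names(photons)) photons$emitter
        else rep(1L, nrow(photons))
  if (nrow(photons) < min_photons)
    stop(sprintf("only %d photons; at least %d recommended for a reliable estimate",
                 nrow(photons), min_photons), call. = FALSE)
  ssx <- 0; ssz <- 0; nx <- 0; nz <- 0
  for (b in seq_len(nrow(bead_positions))) {
    ph <- photons[id == b, ]
    if (!nrow(ph)) next
    ssx <- ssx + sum((ph$x_nm - bead_positions$x_nm[b])^2) +
                 sum((ph$y_nm - bead_positions$y_nm[b])^2)
    nx <- nx + 2L * nrow(ph)
    if ("z_nm" %in% names(ph) && !anyNA(ph$z_nm)) {
      ssz <- ssz + sum((ph$z_nm - bead_positions$z_nm[b])^2)
      nz <- nz + nrow(ph)
    }
  }
  corr <- (bead_diameter / 2)^2 / 5  # uniform sphere second moment per axis
  sxy <- sqrt(max(ssx / nx - corr, 0))
  sz <- if (nz > 0) sqrt(max(ssz / nz - corr, 0)) else NA_real_
  psf_model(sigma_xy = sxy, sigma_z = if (is.na(sz)) sxy else sz)
}
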