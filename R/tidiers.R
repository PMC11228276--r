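#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reconstruction into a voxel table
#'
#' @param x A `reconstruction`.
#' @param drop_zero Drop voxels whose mean, lower and upper are all zero
#'   (default `TRUE`).
#' @param ... Unused.
#' @return A tibble with `x_nm`, `y_nm`, `z_nm` (voxel centres), `mean`,
#'   `lower`, `upper`.
#' @export
tidy.reconstruction <- function(x, drop_zero = TRUE, ...) {
  g <- x$grid
  out <- tidyr::expand_grid(
    z_nm = grid_centers(g, 3), y_nm = grid_centers(g, 2),
    x_nm = grid_centers(g, 1))
  # expand_grid varies the last column fastest; our arrays vary x fastest
  out <- out[c("x_nm", "y_nm", "z_nm")]
  out$mean <- as.vector(x$mean_volume)
  out$lower <- as.vector(x$lower_volume)
  out$upper <- as.vector(x$upper_volume)
  if (drop_zero) out <- out[out$mean > 0 | out$upper > 0, ]
  tibble::as_tibble(out)
}

#' One-row summary of a reconstruction
#'
#' @param x A `reconstruction`.
#' @param ... Unused.
#' @return A tibble with photon and replicate counts, interval level, flux
#'   and the median relative interval width over voxels with positive mean.
#' @export
glance.reconstruction <- function(x, ...) {
  pos <- x$mean_volume > 0
  relw <- if (any(pos))
    stats::median((x$upper_volume[pos] - x$lower_volume[pos]) /
                  x$mean_volume[pos])
  else NA_real_
  tibble::tibble(
    n_photons = x$n_photons, n_replicates = x$n_replicates,
    alpha = x$alpha, flux = sum(x$mean_volume),
    n_voxels = length(x$mean_volume), n_voxels_positive = sum(pos),
    median_rel_interval_width = relw,
    t_start_ms = x$window[1], t_end_ms = x$window[2])
}

#' Tidy an intensity volume
#' @param x An `intensity_volume`.
#' @param drop_zero Drop zero voxels (default `TRUE`).
#' @param ... Unused.
#' @return A tibble with voxel centres and `intensity`.
#' @export
tidy.intensity_volume <- function(x, drop_zero = TRUE, ...) {
  g <- x$grid
  out <- tidyr::expand_grid(
    z_nm = grid_centers(g, 3), y_nm = grid_centers(g, 2),
    x_nm = grid_centers(g, 1))[c("x_nm", "y_nm", "z_nm")]
  out$intensity <- as.vector(x$intensity)
  if (drop_zero) out <- out[out$intensity > 0, ]
  tibble::as_tibble(out)
}
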