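#' Generate ground-truth emitter sets
#'
#' Builds fluorophore positions for the supported test geometries, in
#' object-space nanometres.  Geometries:
#'
#' * `point`: a single emitter (or several, via `positions`).
#' * `line_pair`: two parallel rows of dyes along x, separated by `spacing`
#'   in y and centred on `center` -- the nano-ruler geometry.  Dyes are
#'   placed every `pitch` nm over `length` nm, exactly on the two lines.
#' * `plane_pair`: two parallel rows along x at the same y, separated by
#'   `spacing` along z (for axial resolution tests).
#' * `filament`: a persistent random walk in 3D with step `pitch` and
#'   directional persistence `persistence` in `[0, 1)`; deterministic given
#'   `seed`.
#' * `bead`: `n_beads` point emitters at `positions` (defaults to origin),
#'   tagged so that bead-size corrections can be applied downstream.
#'
#' @param geometry One of `"point"`, `"line_pair"`, `"plane_pair"`,
#'   `"filament"`, `"bead"`.
#' @param spacing Line separation (nm); must be > 0 where used.
#' @param length Line/filament length (nm); must be > 0 where used.
#' @param pitch Dye spacing along a line or filament step (nm).
#' @param center Length-3 numeric, geometry centre (nm).
#' @param axis For `line_pair`/`plane_pair`, the axis of the separation:
#'   `"y"` (default) or `"z"` is implied by the geometry; lines always run
#'   along x.
#' @param brightness Expected detected-photon rate per emitter at focus
#'   (photons/ms); recycled.
#' @param channel Channel label.
#' @param positions Optional matrix/data frame of explicit positions
#'   (`point` and `bead`).
#' @param n_beads Number of beads (`bead` geometry).
#' @param persistence Direction persistence of the filament walk.
#' @param seed RNG seed for stochastic geometries (`filament`).
#' @return A tibble of class `emitter_set` with columns `x_nm`, `y_nm`,
#'   `z_nm`, `brightness`, `channel` and attribute `geometry_tag`.
#' @examples
#' generate_emitters("line_pair", spacing = 71, length = 200, pitch = 5)
#' @export
generate_emitters <- function(geometry = c("point", "line_pair", "plane_pair",
                                           "filament", "bead"),
                              spacing = NULL, length = NULL, pitch = 5,
                              center = c(0, 0, 0), brightness = 1,
                              channel = "ch1", positions = NULL,
                              n_beads = 1, persistence = 0.9, seed = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(length(center) == 3, all(is.finite(center)))
  pos <- switch(geometry,
    point = {
      if (is.null(positions)) matrix(center, nrow = 1)
      else as.matrix(positions)
    },
    line_pair = ,
    plane_pair = {
      if (is.null(spacing) || spacing <= 0)
        stop("`spacing` must be > 0", call. = FALSE)
      if (is.null(length) || length <= 0)
        stop("`length` must be > 0", call. = FALSE)
      xs <- seq(-length / 2, length / 2, by = pitch)
      half <- spacing / 2
      if (geometry == "line_pair") {
        rbind(cbind(xs, -half, 0), cbind(xs, half, 0))
      } else {
        rbind(cbind(xs, 0, -half), cbind(xs, 0, half))
      }
    },
    filament = {
      if (is.null(length) || length <= 0)
        stop("`length` must be > 0", call. = FALSE)
      n_step <- max(2L, as.integer(ceiling(length / pitch)))
      if (!is.null(seed)) withr::local_seed(seed)
      dir <- c(1, 0, 0)
      p <- matrix(0, n_step, 3)
      for (i in 2:n_step) {
        turn <- stats::rnorm(3, sd = 1 - persistence)
        dir <- dir + turn
        dir <- dir / sqrt(sum(dir^2))
        p[i, ] <- p[i - 1, ] + pitch * dir
      }
      p
    },
    bead = {
      if (is.null(positions)) {
        matrix(rep(center, n_beads), ncol = 3, byrow = TRUE)
      } else as.matrix(positions)
    })
  pos <- sweep(pos, 2, if (geometry %in% c("line_pair", "plane_pair")) center else c(0, 0, 0), "+")
  if (!all(is.finite(pos))) stop("emitter positions must be finite", call. = FALSE)
  if (any(brightness < 0)) stop("`brightness` must be >= 0", call. = FALSE)
  out <- tibble::tibble(x_nm = pos[, 1], y_nm = pos[, 2], z_nm = pos[, 3],
                        brightness = rep_len(brightness, nrow(pos)),
                        channel = channel)
  attr(out, "geometry_tag") <- geometry
  class(out) <- c("emitter_set", class(out))
  out
}
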