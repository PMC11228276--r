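#' Write a frame stack as multi-page TIFF with a sidecar
#'
#' One 16-bit page per frame plus a YAML sidecar (`<path>.yml`) carrying
#' `pixel_size_nm`, `frame_interval_ms` and the `dark` flag.
#'
#' @param frames A `frame_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  stopifnot(inherits(frames, "frame_stack"))
  d <- dim(frames$frames)
  maxv <- 65535
  pages <- lapply(seq_len(d[3]), function(f) {
    pmin(pmax(frames$frames[, , f], 0), maxv) / maxv
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- list(pixel_size_nm = frames$pixel_size_nm,
               frame_interval_ms = frames$frame_interval_ms,
               dark = isTRUE(frames$dark), n_frames = d[3])
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' Read a frame stack written by [write_frames()]
#'
#' @param path TIFF path; the `<path>.yml` sidecar must exist (or metadata
#'   must be supplied).
#' @param pixel_size_nm,frame_interval_ms Override/supply metadata for
#'   externally produced stacks without a sidecar.
#' @return A `frame_stack`.
#' @export
read_frames <- function(path, pixel_size_nm = NULL, frame_interval_ms = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]]
  side <- paste0(path, ".yml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  ps <- pixel_size_nm %||% meta$pixel_size_nm
  fi <- frame_interval_ms %||% meta$frame_interval_ms
  if (is.null(ps) || is.null(fi))
    stop("no sidecar metadata; supply pixel_size_nm and frame_interval_ms",
         call. = FALSE)
  frame_stack(arr, pixel_size_nm = ps, frame_interval_ms = fi,
              dark = isTRUE(meta$dark))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a photon table to CSV
#'
#' Canonical exchange format: header
#' `x_nm,y_nm,z_nm,t_ms,frame,amplitude,residual,channel` (missing columns
#' are written as `NA`); ground-truth tables keep their `emitter` column as
#' a trailing column.
#'
#' @param photons A photon table tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_photons <- function(photons, path) {
  photons <- tibble::as_tibble(photons)
  cols <- c("x_nm", "y_nm", "z_nm", "t_ms", "frame", "amplitude",
            "residual", "channel")
  if ("emitter" %in% names(photons)) cols <- c(cols, "emitter")
  for (cl in setdiff(cols, names(photons))) photons[[cl]] <- NA
  readr::write_csv(photons[cols], path)
  invisible(path)
}

#' Read a photon table CSV
#'
#' @param path CSV path with the [write_photons()] header.
#' @return A `photon_table` tibble.
#' @export
read_photons <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           x_nm = "d", y_nm = "d", z_nm = "d", t_ms = "d",
                           frame = "i", amplitude = "d", residual = "d",
                           channel = "c", .default = "d"))
  class(out) <- c("photon_table", class(out))
  out
}

#' Write a camera calibration
#'
#' Two 32-bit float TIFF pages (offset, sigma) plus a YAML sidecar with the
#' threshold factor and hot-pixel list.
#'
#' @param calib A [calibrate_camera()] result.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "camera_calibration"))
  scale <- 65535
  tiff::writeTIFF(list(calib$offset / scale, calib$sigma / scale), path,
                  bits.per.sample = 32, compression = "none")
  hot <- which(calib$hot, arr.ind = TRUE)
  yaml::write_yaml(list(k = calib$k, scale = scale, n_frames = calib$n_frames,
                        pixel_size_nm = calib$pixel_size_nm,
                        hot_pixels = if (nrow(hot))
                          lapply(seq_len(nrow(hot)), function(i)
                            list(row = unname(hot[i, 1]), col = unname(hot[i, 2])))
                        else list()),
                  paste0(path, ".yml"))
  invisible(path)
}

#' Read a camera calibration written by [write_calibration()]
#' @param path TIFF path.
#' @return A `camera_calibration`.
#' @export
read_calibration <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  offset <- pages[[1]] * meta$scale
  sigma <- pages[[2]] * meta$scale
  hot <- matrix(FALSE, nrow(offset), ncol(offset))
  for (h in meta$hot_pixels) hot[h$row, h$col] <- TRUE
  structure(list(offset = offset, sigma = sigma, hot = hot, k = meta$k,
                 n_frames = meta$n_frames, pixel_size_nm = meta$pixel_size_nm),
            class = "camera_calibration")
}

#' Write a reconstruction to TIFF volumes with a manifest
#'
#' Writes one multi-page 32-bit float TIFF per band (mean, lower, upper; z
#' pages) and a YAML manifest describing the grid, window, interval settings
#' and the MD5 hash of every file written.
#'
#' @param recon A `reconstruction`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Manifest path, invisibly.
#' @export
write_volumes <- function(recon, dir, prefix = "volume") {
  stopifnot(inherits(recon, "reconstruction"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bands <- list(mean = recon$mean_volume, lower = recon$lower_volume,
                upper = recon$upper_volume)
  scale <- max(recon$upper_volume, recon$mean_volume, 1e-12)
  files <- character(0)
  for (b in names(bands)) {
    f <- file.path(dir, sprintf("%s_%s.tif", prefix, b))
    v <- bands[[b]]
    pages <- lapply(seq_len(dim(v)[3]), function(k)
      pmin(pmax(t(v[, , k]) / scale, 0), 1))
    tiff::writeTIFF(pages, f, bits.per.sample = 32, compression = "none")
    files <- c(files, f)
  }
  manifest <- file.path(dir, sprintf("%s_manifest.yml", prefix))
  g <- recon$grid
  yaml::write_yaml(list(
    grid = list(xlim = g$xlim, ylim = g$ylim, zlim = g$zlim,
                voxel_size = g$voxel_size, shape = g$shape),
    window_ms = as.numeric(recon$window),
    n_photons = recon$n_photons, n_replicates = recon$n_replicates,
    alpha = recon$alpha, intensity_scale = scale,
    files = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f))))), manifest)
  invisible(manifest)
}
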