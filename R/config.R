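#' Read and validate a pipeline configuration
#'
#' The configuration is YAML with blocks `camera`, `ii`, `psf`, `waveform`,
#' `emitters`, `counting`, `reconstruct`, plus top-level `seed` and
#' `outdir`.  A minimal config needs only `camera` and `waveform`; every
#' other block is filled with defaults.  Unknown keys anywhere are errors
#' (strict mode), and invariant violations name the offending key.
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config` list with all defaults filled.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' Write a pipeline configuration
#' @param config A `pipeline_config` (or compatible list).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

config_defaults <- function() {
  list(
    camera = list(rows = 64L, cols = 64L, pixel_size_nm = 20,
                  frame_interval_ms = 1, read_noise_sigma = 2, offset = 100,
                  bit_depth = 16L),
    ii = list(gain_mean = 800, gain_shape = 2, spot_sigma = 1),
    psf = list(sigma_xy_nm = 110, sigma_z_nm = 300),
    waveform = list(mode = "static", z_range_nm = 0, pitch_nm = 1,
                    plane_interval_ms = 1, blank_ms = 0, pattern = "consecutive"),
    emitters = list(geometry = "point", spacing_nm = 71, length_nm = 200,
                    pitch_nm = 5, brightness = 2, duration_ms = 100,
                    center_nm = c(0, 0, 0)),
    counting = list(enabled = TRUE, k = 5, method = "gauss",
                    ratio_low = NA, ratio_high = NA, min_amplitude = 0,
                    isolation = TRUE, n_dark_frames = 200,
                    photon_csv = NA),
    reconstruct = list(voxel_xy_nm = 20, voxel_z_nm = NA, n_iter = 200,
                       tol = 1e-6, B = 50, alpha = 0.05),
    seed = 1L,
    outdir = "photonrestore-out")
}

validate_config <- function(raw) {
  defs <- config_defaults()
  known_blocks <- names(defs)
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- defs
  for (blk in names(raw)) {
    if (!is.list(defs[[blk]])) { cfg[[blk]] <- raw[[blk]]; next }
    bad <- setdiff(names(raw[[blk]]), names(defs[[blk]]))
    if (length(bad))
      stop(sprintf("unknown key(s) in `%s`: %s", blk,
                   paste(bad, collapse = ", ")), call. = FALSE)
    cfg[[blk]][names(raw[[blk]])] <- raw[[blk]]
  }
  must_pos <- list(
    c("camera", "pixel_size_nm"), c("camera", "frame_interval_ms"),
    c("ii", "gain_mean"), c("ii", "gain_shape"), c("ii", "spot_sigma"),
    c("psf", "sigma_xy_nm"), c("psf", "sigma_z_nm"),
    c("reconstruct", "voxel_xy_nm"),
    c("emitters", "duration_ms"))
  for (key in must_pos) {
    v <- cfg[[key[1]]][[key[2]]]
    if (!is.numeric(v) || v <= 0)
      stop(sprintf("config key `%s.%s` must be > 0", key[1], key[2]),
           call. = FALSE)
  }
  if (cfg$waveform$mode != "static") {
    if (cfg$waveform$pitch_nm <= 0)
      stop("config key `waveform.pitch_nm` must be > 0", call. = FALSE)
    if (cfg$waveform$plane_interval_ms <= 0)
      stop("config key `waveform.plane_interval_ms` must be > 0", call. = FALSE)
  }
  if (cfg$camera$read_noise_sigma < 0)
    stop("config key `camera.read_noise_sigma` must be >= 0", call. = FALSE)
  if (!cfg$waveform$mode %in% c("saw", "triangular", "static"))
    stop("config key `waveform.mode` must be saw, triangular or static",
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

config_camera <- function(cfg) {
  camera_model(shape = c(cfg$camera$rows, cfg$camera$cols),
               pixel_size = cfg$camera$pixel_size_nm,
               frame_interval = cfg$camera$frame_interval_ms,
               read_noise_sigma = cfg$camera$read_noise_sigma,
               offset = cfg$camera$offset, bit_depth = cfg$camera$bit_depth)
}

config_waveform <- function(cfg) {
  w <- cfg$waveform
  if (w$mode == "static") return(scan_waveform("static",
                                               plane_interval = w$plane_interval_ms))
  scan_waveform(w$mode, z_range = w$z_range_nm, pitch = w$pitch_nm,
                plane_interval = w$plane_interval_ms, blank = w$blank_ms)
}
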