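#' Write a PC series as NIfTI-1 with a JSON sidecar
#'
#' The velocity series is stored as a 4D float NIfTI volume ordered
#' (x, y, 1, t) with velocities in cm/s; acquisition parameters and frame
#' times go into a JSON sidecar next to the image (same stem, `.json`).
#'
#' @param series A `pc_series`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, the sidecar path.
#' @export
write_pc_series <- function(series, path) {
  stopifnot(inherits(series, "pc_series"))
  d <- dim(series$velocity_cm_s)                      # frames x rows x cols
  vol <- aperm(series$velocity_cm_s, c(3, 2, 1))      # x(col), y(row), t
  dim(vol) <- c(d[3], d[2], 1L, d[1])
  img <- RNifti::asNifti(vol)
  img <- RNifti::`pixdim<-`(img, c(series$params$pixel_spacing_mm[2],
                                   series$params$pixel_spacing_mm[1],
                                   series$params$slice_thickness_mm,
                                   series$params$frame_interval_ms / 1000))
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- unclass(series$params)
  meta$frame_times_s <- series$frame_times_s
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a PC series written by [write_pc_series()]
#'
#' @param path Path to the `.nii`/`.nii.gz` image; the JSON sidecar is
#'   expected alongside it.
#' @return A `pc_series`.
#' @export
read_pc_series <- function(path) {
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar))
    stop_invalid("sidecar '%s' not found", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  vol <- as.array(RNifti::readNifti(path))
  d <- dim(vol)                                       # x, y, 1, t
  vel <- aperm(array(vol, dim = c(d[1], d[2], d[4])), c(3, 2, 1))
  params <- acquisition_params(
    pixel_spacing_mm = meta$pixel_spacing_mm,
    slice_thickness_mm = meta$slice_thickness_mm,
    frame_interval_ms = meta$frame_interval_ms,
    venc_cm_s = meta$venc_cm_s,
    noise_sd_cm_s = meta$noise_sd_cm_s,
    temporal_window_ms = meta$temporal_window_ms,
    grid_size = meta$grid_size,
    seed = meta$seed,
    spatial_smooth = meta$spatial_smooth,
    aliasing = meta$aliasing,
    subpixel = meta$subpixel)
  structure(list(velocity_cm_s = vel,
                 frame_times_s = meta$frame_times_s,
                 params = params),
            class = "pc_series")
}

#' Write / read a CW Doppler trace as 2-column CSV
#'
#' Columns are `time_s` and `velocity_cm_s`. `read_cw_trace()` needs the beat
#' length to delimit beats; it defaults to treating the whole trace as the
#' stated number of beats.
#'
#' @param trace A `cw_trace`.
#' @param path CSV path.
#' @export
write_cw_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cw_trace"))
  write.csv(data.frame(time_s = trace$time_s,
                       velocity_cm_s = trace$envelope_cm_s),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cw_trace
#' @param cycle_s Beat duration in seconds; if `NULL`, the whole trace is one
#'   beat.
#' @export
read_cw_trace <- function(path, cycle_s = NULL) {
  df <- read.csv(path)
  if (!all(c("time_s", "velocity_cm_s") %in% names(df)))
    stop_invalid("CW trace CSV needs columns 'time_s' and 'velocity_cm_s'")
  total <- max(df$time_s)
  if (is.null(cycle_s)) cycle_s <- total
  structure(list(time_s = df$time_s, envelope_cm_s = df$velocity_cm_s,
                 cycle_s = cycle_s,
                 n_beats = max(1L, as.integer(round(total / cycle_s)))),
            class = "cw_trace")
}

#' Read an experiment configuration from YAML or JSON
#'
#' Accepts the config schema used by [run_grid()]: top-level keys `pump`
#' (`stroke_volumes_ml`, `heart_rate_bpm`, `shape`, `filling_fraction`),
#' `valves` (list of `{size_mm, occluders, aoa_cm2, cc}`), `acquisition`
#' (any [acquisition_params()] argument) and `doppler` (`n_beats`,
#' `noise_sd_cm_s`, `dt_ms`, `broadening`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_experiment_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}
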