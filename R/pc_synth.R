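#' Phase-contrast acquisition parameters
#'
#' Bundles the acquisition settings used when synthesizing a PC velocity-map
#' series. Defaults mirror a clinical segmented PC protocol for transmitral
#' flow: 1.2 x 0.9 mm in-plane resolution, 4 mm slice, 48.9 ms temporal
#' resolution with full-frame temporal averaging, VENC 400 cm/s and 3 cm/s
#' Gaussian velocity noise on a 64 x 64 grid.
#'
#' @param pixel_spacing_mm Length-2 numeric, (row, col) in-plane spacing (mm).
#' @param slice_thickness_mm Through-plane slice thickness (mm).
#' @param frame_interval_ms Temporal resolution (ms/frame).
#' @param venc_cm_s Velocity-encoding ceiling (cm/s); velocities beyond it
#'   wrap modulo 2*VENC when `aliasing = TRUE`.
#' @param noise_sd_cm_s SD of per-pixel Gaussian velocity noise (cm/s); 0
#'   disables noise.
#' @param temporal_window_ms Boxcar averaging window centred on each frame
#'   time (ms). May exceed `frame_interval_ms` (view sharing); 0 means
#'   instantaneous sampling.
#' @param grid_size Length-2 integer, (rows, cols).
#' @param seed RNG seed used for the noise field.
#' @param spatial_smooth Apply a 3 x 3 boxcar to each frame (a simple
#'   partial-volume / reconstruction-smoothing model). Default `TRUE`.
#' @param aliasing Wrap velocities beyond VENC. Default `FALSE` (a VENC chosen
#'   above the expected jet velocity, as in clinical practice).
#' @param subpixel Odd integer; each pixel value is the mean of
#'   `subpixel^2` sub-samples of the jet profile (in-plane partial-volume
#'   model). Default 3.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(pixel_spacing_mm = c(1.2, 0.9),
                               slice_thickness_mm = 4,
                               frame_interval_ms = 48.9,
                               venc_cm_s = 400,
                               noise_sd_cm_s = 3,
                               temporal_window_ms = 48.9,
                               grid_size = c(64L, 64L),
                               seed = 42L,
                               spatial_smooth = TRUE,
                               aliasing = FALSE,
                               subpixel = 3L) {
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0))
    stop_invalid("'pixel_spacing_mm' must be two positive numbers (row, col)")
  check_scalar_pos(slice_thickness_mm, "slice_thickness_mm")
  check_scalar_pos(frame_interval_ms, "frame_interval_ms")
  check_scalar_pos(venc_cm_s, "venc_cm_s")
  if (noise_sd_cm_s < 0) stop_invalid("'noise_sd_cm_s' must be >= 0")
  if (temporal_window_ms < 0) stop_invalid("'temporal_window_ms' must be >= 0")
  if (length(grid_size) != 2L || any(grid_size < 8))
    stop_invalid("'grid_size' must be two integers >= 8")
  structure(list(pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 slice_thickness_mm = slice_thickness_mm,
                 frame_interval_ms = frame_interval_ms,
                 venc_cm_s = venc_cm_s,
                 noise_sd_cm_s = noise_sd_cm_s,
                 temporal_window_ms = temporal_window_ms,
                 grid_size = as.integer(grid_size),
                 seed = as.integer(seed),
                 spatial_smooth = isTRUE(spatial_smooth),
                 aliasing = isTRUE(aliasing),
                 subpixel = as.integer(subpixel)),
            class = "acquisition_params")
}

#' Pixel area of an acquisition (cm^2)
#' @param params An [acquisition_params()].
#' @export
pixel_area_cm2 <- function(params) {
  prod(params$pixel_spacing_mm) / 100
}

# Solve the jet cross-section for a valve. The through-plane velocity profile
# at the valve tips is modelled as a radially symmetric tanh shoulder,
#   s(r) = 0.5 * (1 - tanh((r - r_mid) / w)),
# with (r_mid, w) chosen jointly so that
#   (a) the profile integrates to the effective area A_eff (the jet carries
#       exactly Q(t) at plateau velocity v(t) = Q/A_eff), and
#   (b) the 10%-of-max level set sits at the anatomic orifice radius
#       sqrt(AOA/pi), so that low-threshold planimetry recovers the AOA.
# The shoulder is the low-velocity convergence/partial-volume skirt between
# the vena contracta and the anatomic orifice rim. Constraint (b) pins
# r_mid = r_anat - k*w (k = atanh(0.8)); the width is then the root of the
# exact radial profile integral minus A_eff, evaluated by quadrature.
jet_geometry <- function(valve, min_width_cm = 0.02) {
  a_eff <- effective_area_cm2(valve)
  r_anat <- sqrt(valve$aoa_cm2 / pi)
  k <- atanh(0.8)                      # 10% level sits at r_mid + k*w
  profile_area <- function(w) {
    r_mid <- r_anat - k * w
    rr <- seq(0, r_anat + 10 * w, length.out = 4096L)
    trapz_int(rr, pi * rr * (1 - tanh((rr - r_mid) / w)))
  }
  g <- function(w) profile_area(w) - a_eff
  w_hi <- r_anat / k * 0.99
  w <- if (g(min_width_cm) <= 0 || g(w_hi) > 0) min_width_cm
       else stats::uniroot(g, c(min_width_cm, w_hi), tol = 1e-10)$root
  r_mid <- r_anat - k * w
  list(r_mid_cm = r_mid, width_cm = w, r_anat_cm = r_anat,
       r_10pct_cm = r_mid + k * w)
}

# static spatial pattern of the jet on the pixel grid (frame value is
# v_bar(t) * pattern + noise); normalized so sum(pattern)*pixel_area = A_eff
jet_pattern <- function(valve, params) {
  geom <- jet_geometry(valve)
  nr <- params$grid_size[1]; nc <- params$grid_size[2]
  dy <- params$pixel_spacing_mm[1] / 10   # cm
  dx <- params$pixel_spacing_mm[2] / 10
  half_y <- nr * dy / 2; half_x <- nc * dx / 2
  if (geom$r_10pct_cm + 2 * max(dx, dy) > min(half_x, half_y))
    stop_invalid("jet (radius %.2f cm) does not fit the %d x %d grid",
                 geom$r_10pct_cm, nr, nc)
  if (2 * geom$r_mid_cm * 3 > 2 * min(half_x, half_y))
    warning("grid extent is below 3x the jet diameter; edge effects likely")
  ns <- max(1L, params$subpixel)
  offs <- (seq_len(ns) - (ns + 1) / 2) / ns
  y0 <- (seq_len(nr) - (nr + 1) / 2) * dy
  x0 <- (seq_len(nc) - (nc + 1) / 2) * dx
  pat <- matrix(0, nr, nc)
  for (oy in offs) for (ox in offs) {
    y <- y0 + oy * dy
    x <- x0 + ox * dx
    r <- sqrt(outer(y^2, x^2, `+`))
    pat <- pat + 0.5 * (1 - tanh((r - geom$r_mid_cm) / geom$width_cm))
  }
  pat <- pat / ns^2
  pat * effective_area_cm2(valve) / (sum(pat) * pixel_area_cm2(params))
}

# boxcar time-average of the true jet velocity around each frame time
frame_mean_velocity <- function(waveform, valve, frame_times_s, window_s) {
  v <- true_velocity_trace(waveform, valve)
  if (window_s <= 0)
    return(approx(v$time_s, v$v_cm_s, frame_times_s, rule = 2)$y)
  cum <- cumtrapz_int(v$time_s, v$v_cm_s)
  cfun <- function(tt) approx(v$time_s, cum, tt, rule = 2)$y
  (cfun(frame_times_s + window_s / 2) - cfun(frame_times_s - window_s / 2)) / window_s
}

#' Synthesize a phase-contrast velocity-map series
#'
#' Generates the 4D (frames x rows x cols) through-plane velocity series a PC
#' acquisition would record for a given waveform and valve, imaging plane
#' perpendicular to the inflow jet at the level of the valve tips. Each frame
#' is a centred circular jet whose plateau velocity is the boxcar time-average
#' of the true jet velocity over `temporal_window_ms`, with a tanh shoulder
#' whose extent encodes the anatomic orifice (the convergence skirt between
#' vena contracta and orifice rim; see the methods vignette), per-pixel
#' Gaussian noise, optional 3 x 3
#' spatial smoothing and optional VENC wrap-around. Bit-reproducible for a
#' fixed `params$seed`.
#'
#' @param waveform A [generate_diastolic_waveform()] result.
#' @param valve A [valve_model()].
#' @param params An [acquisition_params()].
#' @return An object of class `pc_series`: list with `velocity_cm_s`
#'   (array frames x rows x cols), `frame_times_s`, `params`.
#' @export
synthesize_pc_series <- function(waveform, valve, params = acquisition_params()) {
  stopifnot(inherits(waveform, "flow_waveform"), inherits(valve, "valve_model"),
            inherits(params, "acquisition_params"))
  cycle_s <- 60 / waveform$heart_rate_bpm
  dt <- params$frame_interval_ms / 1000
  n_frames <- max(2L, floor(cycle_s / dt + 1e-9))
  frame_times <- (seq_len(n_frames) - 0.5) * dt
  vbar <- frame_mean_velocity(waveform, valve, frame_times,
                              params$temporal_window_ms / 1000)
  pat <- jet_pattern(valve, params)
  nr <- params$grid_size[1]; nc <- params$grid_size[2]
  vel <- array(0, dim = c(n_frames, nr, nc))
  set.seed(params$seed)
  for (k in seq_len(n_frames)) {
    fr <- vbar[k] * pat
    if (params$noise_sd_cm_s > 0)
      fr <- fr + matrix(rnorm(nr * nc, sd = params$noise_sd_cm_s), nr, nc)
    if (params$spatial_smooth) fr <- smooth3x3(fr)
    if (params$aliasing) {
      venc <- params$venc_cm_s
      fr <- ((fr + venc) %% (2 * venc)) - venc
    }
    vel[k, , ] <- fr
  }
  structure(list(velocity_cm_s = vel, frame_times_s = frame_times,
                 params = params),
            class = "pc_series")
}

#' @export
print.pc_series <- function(x, ...) {
  d <- dim(x$velocity_cm_s)
  cat(sprintf("PC velocity-map series: %d frames of %d x %d pixels\n",
              d[1], d[2], d[3]))
  cat(sprintf("  pixel %.1f x %.1f mm, slice %.1f mm, %.1f ms/frame, VENC %g cm/s\n",
              x$params$pixel_spacing_mm[1], x$params$pixel_spacing_mm[2],
              x$params$slice_thickness_mm, x$params$frame_interval_ms,
              x$params$venc_cm_s))
  cat(sprintf("  peak pixel velocity %.1f cm/s\n", max(x$velocity_cm_s)))
  invisible(x)
}

#' @export
plot.pc_series <- function(x, frame = NULL, ...) {
  if (is.null(frame)) {
    sums <- apply(x$velocity_cm_s, 1, sum)
    frame <- which.max(sums)
  }
  graphics::image(t(x$velocity_cm_s[frame, , ])[, dim(x$velocity_cm_s)[2]:1],
                  col = grDevices::hcl.colors(64, "viridis"), axes = FALSE,
                  main = sprintf("PC frame %d (t = %.0f ms)",
                                 frame, 1000 * x$frame_times_s[frame]), ...)
  invisible(x)
}

#' Synthesize a continuous-wave Doppler envelope trace
#'
#' Models the CW Doppler maximal-velocity envelope of transmitral inflow with
#' axial beam alignment: the true jet velocity scaled by a spectral-broadening
#' factor (CW envelopes track the upper edge of the spectrum and overread the
#' true maximum by a few percent), plus Gaussian noise, clipped at zero. The
#' trace is sampled far finer than any PC frame interval, reflecting CW
#' Doppler's near-continuous temporal resolution, and may span several
#' identical pump beats whose only beat-to-beat variability is noise.
#'
#' @param waveform A [generate_diastolic_waveform()] result.
#' @param valve A [valve_model()].
#' @param noise_sd_cm_s Gaussian envelope noise SD (cm/s).
#' @param dt_ms Sampling step (ms), must be <= 5.
#' @param seed RNG seed.
#' @param n_beats Number of consecutive beats in the trace (default 5).
#' @param broadening Fractional spectral-broadening overestimation of the
#'   envelope (default 0.05).
#' @param clip_negative Clip the envelope at 0 (default `TRUE`).
#' @return Object of class `cw_trace`: list with `time_s`, `envelope_cm_s`,
#'   `cycle_s`, `n_beats`.
#' @export
synthesize_cw_trace <- function(waveform, valve, noise_sd_cm_s = 3,
                                dt_ms = 2, seed = 42L, n_beats = 5L,
                                broadening = 0.05, clip_negative = TRUE) {
  stopifnot(inherits(waveform, "flow_waveform"), inherits(valve, "valve_model"))
  if (dt_ms <= 0 || dt_ms > 5)
    stop_invalid("'dt_ms' must be positive and at most 5 ms")
  if (noise_sd_cm_s < 0) stop_invalid("'noise_sd_cm_s' must be >= 0")
  if (n_beats < 1) stop_invalid("'n_beats' must be >= 1")
  cycle_s <- 60 / waveform$heart_rate_bpm
  v <- true_velocity_trace(waveform, valve)
  dt <- dt_ms / 1000
  tt <- seq(0, by = dt, length.out = ceiling(n_beats * cycle_s / dt) + 1L)
  base <- (1 + broadening) * approx(v$time_s, v$v_cm_s, tt %% cycle_s, rule = 2)$y
  set.seed(seed)
  env <- base + if (noise_sd_cm_s > 0) rnorm(length(tt), sd = noise_sd_cm_s) else 0
  if (clip_negative) env[env < 0] <- 0
  structure(list(time_s = tt, envelope_cm_s = env,
                 cycle_s = cycle_s, n_beats = as.integer(n_beats)),
            class = "cw_trace")
}

#' @export
print.cw_trace <- function(x, ...) {
  cat(sprintf("CW Doppler envelope: %d beats, %d samples (%.1f ms step)\n",
              x$n_beats, length(x$time_s), 1000 * diff(x$time_s[1:2])))
  cat(sprintf("  peak envelope velocity %.1f cm/s\n", max(x$envelope_cm_s)))
  invisible(x)
}

#' @export
plot.cw_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$envelope_cm_s, type = "l",
                 xlab = "time (s)", ylab = "velocity (cm/s)",
                 main = "CW Doppler envelope", ...)
  invisible(x)
}
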