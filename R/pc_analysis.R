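#' Segment the transmitral jet in a PC series
#'
#' Semi-automatic jet segmentation: the reference frame is the frame of
#' greatest spatial-sum velocity; the velocity threshold is
#' `threshold_fraction` times the reference frame's maximum. Each frame's mask
#' is the largest 4-connected component of supra-threshold pixels; frames with
#' no supra-threshold pixel (late diastole/systole) inherit the reference
#' frame's mask so every frame has a region to integrate over.
#'
#' @param series A `pc_series`.
#' @param threshold_fraction Fraction of the reference-frame maximum, in
#'   (0, 1). Use ~0.5 to isolate the vena-contracta-like jet core, ~0.1 to
#'   capture the full jet base.
#' @return Object of class `roi_mask_series`: list with `mask` (logical array
#'   frames x rows x cols) and `source = "threshold"`.
#' @export
segment_jet_roi <- function(series, threshold_fraction = 0.5) {
  stopifnot(inherits(series, "pc_series"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop_invalid("'threshold_fraction' must lie strictly between 0 and 1")
  vel <- series$velocity_cm_s
  if (all(vel == 0) || max(vel) <= 0)
    stop_invalid("no jet detected: series has no positive velocities")
  sums <- apply(vel, 1, sum)
  ref <- which.max(sums)
  thr <- threshold_fraction * max(vel[ref, , ])
  n_frames <- dim(vel)[1]
  mask <- array(FALSE, dim = dim(vel))
  ref_mask <- largest_component(vel[ref, , ] >= thr)
  for (k in seq_len(n_frames)) {
    cand <- vel[k, , ] >= thr
    mask[k, , ] <- if (any(cand)) largest_component(cand) else ref_mask
  }
  structure(list(mask = mask, source = "threshold",
                 reference_frame = ref, threshold_cm_s = thr),
            class = "roi_mask_series")
}

#' Grow an ROI mask series
#'
#' Dilates every frame's mask by `pixels` (square structuring element). Flow
#' integration uses a grown mask so the smooth jet shoulder outside the
#' threshold level set is not clipped — the in-silico analog of drawing the
#' contour generously around the jet.
#'
#' @param roi A `roi_mask_series`.
#' @param pixels Dilation radius in pixels.
#' @return A `roi_mask_series`.
#' @export
grow_roi <- function(roi, pixels = 4L) {
  stopifnot(inherits(roi, "roi_mask_series"))
  out <- roi
  for (k in seq_len(dim(roi$mask)[1]))
    out$mask[k, , ] <- dilate_mask(roi$mask[k, , ], pixels)
  out
}

#' Instantaneous transvalvular flow from a PC series
#'
#' For each frame, sums velocity (cm/s) over the ROI and multiplies by the
#' pixel area (cm^2), giving volumetric flow in mL/s.
#'
#' @param series A `pc_series`.
#' @param roi A `roi_mask_series` of matching shape.
#' @return Data frame with `time_s` and `flow_ml_s` per frame.
#' @export
instantaneous_flow <- function(series, roi) {
  stopifnot(inherits(series, "pc_series"), inherits(roi, "roi_mask_series"))
  if (!identical(dim(series$velocity_cm_s), dim(roi$mask)))
    stop_invalid("series and ROI shapes disagree")
  a_pix <- pixel_area_cm2(series$params)
  n_frames <- dim(series$velocity_cm_s)[1]
  flow <- vapply(seq_len(n_frames), function(k) {
    m <- roi$mask[k, , ]
    if (!any(m)) 0 else sum(series$velocity_cm_s[k, , ][m]) * a_pix
  }, numeric(1))
  data.frame(time_s = series$frame_times_s, flow_ml_s = flow)
}

#' Forward flow volume (FFV)
#'
#' Trapezoidal time-integral of positive flow over the whole cycle, in
#' mL/beat: negative flows are clipped at zero and every frame contributes,
#' so no filling-phase frame is lost at the window edges. (Flow outside the
#' filling phase is zero up to clipped noise, whose contribution is
#' negligible; the floor-gated filling window is reserved for the TVI, where
#' it matters.)
#'
#' @param flow_trace Data frame with `time_s`, `flow_ml_s` (at least 2 rows).
#' @return FFV in mL.
#' @export
forward_flow_volume <- function(flow_trace) {
  if (nrow(flow_trace) < 2L)
    stop_invalid("at least 2 frames are required to integrate flow")
  q <- pmax(flow_trace$flow_ml_s, 0)
  trapz_int(flow_trace$time_s, q)
}

#' Per-frame peak velocity within the ROI
#'
#' Maximum (or an upper percentile, to temper noise-inflated maxima) of the
#' velocity within each frame's ROI. Frames with an empty mask report 0.
#'
#' @param series A `pc_series`.
#' @param roi A `roi_mask_series`.
#' @param percentile Upper percentile in (0, 100]; 100 (default) is the max.
#' @return Data frame with `time_s`, `v_cm_s`.
#' @export
peak_velocity_trace <- function(series, roi, percentile = 100) {
  stopifnot(inherits(series, "pc_series"), inherits(roi, "roi_mask_series"))
  if (!identical(dim(series$velocity_cm_s), dim(roi$mask)))
    stop_invalid("series and ROI shapes disagree")
  if (percentile <= 0 || percentile > 100)
    stop_invalid("'percentile' must lie in (0, 100]")
  n_frames <- dim(series$velocity_cm_s)[1]
  v <- vapply(seq_len(n_frames), function(k) {
    m <- roi$mask[k, , ]
    if (!any(m)) return(0)
    vals <- series$velocity_cm_s[k, , ][m]
    if (percentile >= 100) max(vals)
    else unname(quantile(vals, percentile / 100, type = 7))
  }, numeric(1))
  data.frame(time_s = series$frame_times_s, v_cm_s = v)
}

#' Time-velocity integral (TVI)
#'
#' Trapezoidal integral of the peak-velocity trace (cm/s over s, giving cm),
#' restricted to the filling window. The window core is the longest
#' contiguous run of samples above `floor_fraction` of the trace maximum
#' (the floor rejects diastasis/systolic noise); from each end the envelope
#' is then traced outward to baseline through monotonically decaying positive
#' samples, as a reader closes an envelope tracing. An all-zero trace
#' yields 0.
#'
#' @param velocity_trace Data frame with `time_s`, `v_cm_s` (>= 2 rows).
#' @param floor_fraction Fraction of the trace maximum below which samples
#'   are excluded (default 0.05).
#' @return TVI in cm.
#' @export
time_velocity_integral <- function(velocity_trace, floor_fraction = 0.05) {
  if (nrow(velocity_trace) < 2L)
    stop_invalid("at least 2 samples are required to integrate velocity")
  v <- velocity_trace$v_cm_s
  if (max(v) <= 0) return(0)
  idx <- longest_run(v >= floor_fraction * max(v))
  if (length(idx) < 2L) return(0)
  lo <- idx[1]; hi <- idx[length(idx)]
  while (lo > 1L && v[lo - 1L] > 0 && v[lo - 1L] <= v[lo]) lo <- lo - 1L
  while (hi < length(v) && v[hi + 1L] > 0 && v[hi + 1L] <= v[hi]) hi <- hi + 1L
  idx <- seq.int(max(1L, lo - 1L), min(length(v), hi + 1L))
  trapz_int(velocity_trace$time_s[idx], v[idx])
}

#' Phase-contrast effective orifice area
#'
#' `EOA = FFV / TVI` (cm^3 / cm = cm^2): the mean diastolic flow area at the
#' plane of maximal velocities.
#'
#' @param ffv_ml Forward flow volume (mL).
#' @param tvi_cm Time-velocity integral (cm), > 0.
#' @return EOA in cm^2.
#' @examples
#' pc_eoa(90, 60)  # 1.5
#' @export
pc_eoa <- function(ffv_ml, tvi_cm) {
  if (!is.finite(tvi_cm) || tvi_cm <= 0)
    stop_invalid("'tvi_cm' must be positive to derive an EOA")
  if (ffv_ml < 0) stop_invalid("'ffv_ml' must be non-negative")
  ffv_ml / tvi_cm
}

#' Planimetric anatomic orifice area
#'
#' Single-frame planimetry at the frame of peak flow: the jet mask at a low
#' threshold (default 10% of the frame maximum, capturing the full anatomic
#' jet base including the slow convergence skirt) is pixel-counted and scaled
#' by the pixel area. The low threshold is deliberate: AOA measures the
#' anatomic opening, whereas the EOA jet core corresponds to a ~50% threshold.
#'
#' @param series A `pc_series`.
#' @param threshold_fraction Fraction of the peak-frame maximum (default 0.1).
#' @return AOA in cm^2.
#' @export
planimeter_aoa <- function(series, threshold_fraction = 0.1) {
  roi <- segment_jet_roi(series, threshold_fraction)
  ref <- roi$reference_frame
  sum(roi$mask[ref, , ]) * pixel_area_cm2(series$params)
}

#' Simplified-Bernoulli pressure gradients
#'
#' Converts a jet-velocity trace (cm/s) to transvalvular pressure gradients
#' via the simplified Bernoulli relation `dP = 4 v^2` with v in m/s: peak
#' gradient from the trace maximum, mean gradient as the time average of
#' `4 v(t)^2` over the filling window (samples above `floor_fraction` of the
#' trace maximum).
#'
#' @param velocity_trace Data frame with `time_s`, `v_cm_s`.
#' @param floor_fraction Filling-window floor (default 0.05).
#' @return Named list with `peak_gradient_mmhg`, `mean_gradient_mmhg`.
#' @examples
#' tr <- data.frame(time_s = c(0, 1), v_cm_s = c(200, 200))
#' bernoulli_gradients(tr)  # both 16 mmHg
#' @export
bernoulli_gradients <- function(velocity_trace, floor_fraction = 0.05) {
  v <- velocity_trace$v_cm_s
  if (max(v) <= 0)
    return(list(peak_gradient_mmhg = 0, mean_gradient_mmhg = 0))
  peak <- 4 * (max(v) / 100)^2
  idx <- longest_run(v >= floor_fraction * max(v))
  grad <- 4 * (v[idx] / 100)^2
  mean_g <- if (length(idx) < 2L) mean(grad)
            else trapz_int(velocity_trace$time_s[idx], grad) /
                 diff(range(velocity_trace$time_s[idx]))
  list(peak_gradient_mmhg = peak, mean_gradient_mmhg = mean_g)
}

#' Valve summary constructor
#'
#' One row of hemodynamic indices for a valve under one flow condition, as
#' measured by one method.
#'
#' @param method `"PC"`, `"Doppler"` or `"reference"`.
#' @param peak_velocity_cm_s,tvi_cm,ffv_ml,eoa_cm2 Core indices (>= 0).
#' @param aoa_cm2 Planimetric anatomic area (PC/reference only; `NA`
#'   otherwise).
#' @param peak_gradient_mmhg,mean_gradient_mmhg Bernoulli gradients.
#' @return Object of class `valve_summary` (also a one-row data frame).
#' @export
valve_summary <- function(method, peak_velocity_cm_s, tvi_cm, ffv_ml, eoa_cm2,
                          aoa_cm2 = NA_real_, peak_gradient_mmhg = NA_real_,
                          mean_gradient_mmhg = NA_real_) {
  method <- match.arg(method, c("PC", "Doppler", "reference"))
  vals <- c(peak_velocity_cm_s, tvi_cm, ffv_ml, eoa_cm2)
  if (any(vals < 0, na.rm = TRUE))
    stop_invalid("hemodynamic indices must be non-negative")
  if (is.finite(peak_gradient_mmhg) && is.finite(mean_gradient_mmhg) &&
      peak_gradient_mmhg < mean_gradient_mmhg - 1e-9)
    stop_invalid("peak gradient cannot be below mean gradient")
  out <- data.frame(method = method,
                    peak_velocity_cm_s = peak_velocity_cm_s,
                    tvi_cm = tvi_cm, ffv_ml = ffv_ml, eoa_cm2 = eoa_cm2,
                    aoa_cm2 = aoa_cm2,
                    peak_gradient_mmhg = peak_gradient_mmhg,
                    mean_gradient_mmhg = mean_gradient_mmhg)
  class(out) <- c("valve_summary", class(out))
  out
}

#' Full PC analysis of a velocity-map series
#'
#' Runs the complete phase-contrast pipeline on one series: jet segmentation
#' at a low threshold (grown by `grow` pixels for flow integration),
#' instantaneous flow, FFV, peak-velocity trace, TVI, `EOA = FFV/TVI`,
#' planimetric AOA, and simplified-Bernoulli gradients.
#'
#' @param series A `pc_series`.
#' @param threshold Segmentation threshold fraction for the flow ROI
#'   (default 0.1).
#' @param aoa_threshold Planimetry threshold fraction (default 0.1).
#' @param grow ROI dilation in pixels before flow summation (default 4).
#' @param percentile Peak-velocity percentile (default 100 = max).
#' @return A [valve_summary()] with `method = "PC"`; the flow and velocity
#'   traces are attached as attribute `"traces"`.
#' @export
analyze_pc <- function(series, threshold = 0.1, aoa_threshold = 0.1,
                       grow = 4L, percentile = 100) {
  roi <- grow_roi(segment_jet_roi(series, threshold), grow)
  flow <- instantaneous_flow(series, roi)
  ffv <- forward_flow_volume(flow)
  vel <- peak_velocity_trace(series, roi, percentile)
  tvi <- time_velocity_integral(vel)
  grads <- bernoulli_gradients(vel)
  out <- valve_summary("PC",
                       peak_velocity_cm_s = max(vel$v_cm_s),
                       tvi_cm = tvi, ffv_ml = ffv,
                       eoa_cm2 = pc_eoa(ffv, tvi),
                       aoa_cm2 = planimeter_aoa(series, aoa_threshold),
                       peak_gradient_mmhg = grads$peak_gradient_mmhg,
                       mean_gradient_mmhg = grads$mean_gradient_mmhg)
  attr(out, "traces") <- list(flow = flow, velocity = vel)
  out
}

#' @export
print.valve_summary <- function(x, ...) {
  cat(sprintf("%s valve summary\n", x$method))
  cat(sprintf("  peak velocity : %8.1f cm/s\n", x$peak_velocity_cm_s))
  cat(sprintf("  TVI           : %8.1f cm\n", x$tvi_cm))
  cat(sprintf("  FFV           : %8.1f mL/beat\n", x$ffv_ml))
  cat(sprintf("  EOA           : %8.2f cm^2\n", x$eoa_cm2))
  if (is.finite(x$aoa_cm2))
    cat(sprintf("  AOA           : %8.2f cm^2\n", x$aoa_cm2))
  if (is.finite(x$peak_gradient_mmhg))
    cat(sprintf("  gradients     : %8.1f / %.1f mmHg (peak/mean)\n",
                x$peak_gradient_mmhg, x$mean_gradient_mmhg))
  invisible(x)
}
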