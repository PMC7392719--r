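#' Doppler indices from a CW envelope trace
#'
#' Splits the trace into beats, computes peak velocity, TVI and
#' simplified-Bernoulli gradients per beat with the same integrators as the
#' PC pipeline, and averages over `n_beats` consecutive beats (clinical
#' practice: five consecutive measurements).
#'
#' @param trace A `cw_trace`.
#' @param n_beats Number of beats to average (default 5); the trace must
#'   cover at least this many cycles.
#' @return Named list with `peak_velocity_cm_s`, `tvi_cm`,
#'   `peak_gradient_mmhg`, `mean_gradient_mmhg`, and the per-beat values in
#'   `per_beat`.
#' @export
doppler_indices <- function(trace, n_beats = 5L) {
  stopifnot(inherits(trace, "cw_trace"))
  if (n_beats < 1) stop_invalid("'n_beats' must be >= 1")
  total <- max(trace$time_s)
  if (total + 1e-9 < n_beats * trace$cycle_s)
    stop_invalid("trace covers %.2f s but %d beats need %.2f s",
                 total, n_beats, n_beats * trace$cycle_s)
  per_beat <- lapply(seq_len(n_beats), function(b) {
    lo <- (b - 1) * trace$cycle_s
    hi <- b * trace$cycle_s
    sel <- trace$time_s >= lo - 1e-12 & trace$time_s <= hi + 1e-12
    tr <- data.frame(time_s = trace$time_s[sel],
                     v_cm_s = trace$envelope_cm_s[sel])
    g <- bernoulli_gradients(tr)
    c(peak_velocity_cm_s = max(tr$v_cm_s),
      tvi_cm = time_velocity_integral(tr),
      peak_gradient_mmhg = g$peak_gradient_mmhg,
      mean_gradient_mmhg = g$mean_gradient_mmhg)
  })
  per_beat <- do.call(rbind, per_beat)
  avg <- colMeans(per_beat)
  c(as.list(avg), list(per_beat = as.data.frame(per_beat)))
}

#' Doppler effective orifice area
#'
#' Continuity-style EOA: the reference forward flow volume (in vitro flow
#' meter; in simulation, the exact waveform integral) divided by the Doppler
#' TVI.
#'
#' @param reference_ffv_ml Reference FFV (mL).
#' @param doppler_tvi_cm Doppler TVI (cm), > 0.
#' @return EOA in cm^2.
#' @examples
#' doppler_eoa(90, 90)  # 1.0
#' @export
doppler_eoa <- function(reference_ffv_ml, doppler_tvi_cm) {
  if (!is.finite(doppler_tvi_cm) || doppler_tvi_cm <= 0)
    stop_invalid("'doppler_tvi_cm' must be positive to derive an EOA")
  if (reference_ffv_ml < 0) stop_invalid("'reference_ffv_ml' must be non-negative")
  reference_ffv_ml / doppler_tvi_cm
}

#' Full Doppler analysis of a CW trace
#'
#' Beat-averaged Doppler indices plus the continuity EOA from a reference
#' forward flow volume.
#'
#' @param trace A `cw_trace`.
#' @param reference_ffv_ml Reference FFV (mL), e.g. the pump stroke volume.
#' @param n_beats Beats to average (default 5).
#' @return A [valve_summary()] with `method = "Doppler"`.
#' @export
analyze_cw <- function(trace, reference_ffv_ml, n_beats = 5L) {
  idx <- doppler_indices(trace, n_beats)
  valve_summary("Doppler",
                peak_velocity_cm_s = idx$peak_velocity_cm_s,
                tvi_cm = idx$tvi_cm,
                ffv_ml = reference_ffv_ml,
                eoa_cm2 = doppler_eoa(reference_ffv_ml, idx$tvi_cm),
                peak_gradient_mmhg = idx$peak_gradient_mmhg,
                mean_gradient_mmhg = idx$mean_gradient_mmhg)
}
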