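#' Ground-truth diastolic flow waveform
#'
#' Constructs the volumetric flow-rate waveform of one cardiac cycle of the
#' pulsatile flow loop. Transmitral filling in the simulated rig is
#' single-phase and strictly forward: flow is non-negative everywhere, nonzero
#' only during the diastolic filling window, and its trapezoidal time integral
#' equals the stroke volume.
#'
#' @param stroke_volume_ml Forward volume per beat (mL), > 0.
#' @param heart_rate_bpm Pump rate (beats/min), > 0.
#' @param filling_fraction Fraction of the cycle occupied by diastolic filling,
#'   in (0, 1). The default 0.75 reflects the long single-phase filling window of the
#'   pulsatile pump; filling starts at t = 0 and the remainder
#'   of the cycle ("systole") carries zero flow.
#' @param shape `"half_sine"` (single half-sinusoid) or `"e_wave"` (raised
#'   cosine E-wave with a lower mid-diastolic hump; see Details).
#' @param n_samples Number of uniformly spaced time samples over the cycle
#'   (>= 64).
#'
#' @details The `e_wave` shape is a raised cosine of relative amplitude 1 over
#' the first 60% of the filling window plus a raised cosine of amplitude 0.35
#' over the last 55%, overlapping, summed and renormalized so the integral is
#' exactly the stroke volume. It mimics early plus mid-diastolic filling; the
#' pump's true waveform shape is a free configuration choice, not a measured
#' quantity.
#'
#' @return An object of class `flow_waveform`: a list with `time_s`,
#'   `flow_ml_s`, `heart_rate_bpm`, `stroke_volume_ml`.
#' @examples
#' wf <- generate_diastolic_waveform(90, 70)
#' pracma::trapz(wf$time_s, wf$flow_ml_s)  # 90
#' @export
generate_diastolic_waveform <- function(stroke_volume_ml, heart_rate_bpm,
                                        filling_fraction = 0.75,
                                        shape = c("half_sine", "e_wave"),
                                        n_samples = 1024L) {
  check_scalar_pos(stroke_volume_ml, "stroke_volume_ml")
  check_scalar_pos(heart_rate_bpm, "heart_rate_bpm")
  shape <- match.arg(shape)
  if (!is.numeric(filling_fraction) || length(filling_fraction) != 1L ||
      filling_fraction <= 0 || filling_fraction >= 1)
    stop_invalid("'filling_fraction' must lie strictly between 0 and 1")
  if (n_samples < 64L) stop_invalid("'n_samples' must be at least 64")

  cycle_s <- 60 / heart_rate_bpm
  t <- seq(0, cycle_s, length.out = n_samples)
  t_fill <- filling_fraction * cycle_s
  u <- t / t_fill                                # 0..1 inside filling window
  q <- numeric(n_samples)
  inside <- u <= 1
  if (shape == "half_sine") {
    q[inside] <- sin(pi * u[inside])
  } else {
    # early (E) lobe over the first 60% of filling, mid-diastolic hump over
    # the last 55%; overlapping raised cosines, summed
    e1 <- ifelse(u >= 0 & u <= 0.6, 0.5 * (1 - cos(2 * pi * u / 0.6)), 0)
    e2 <- ifelse(u >= 0.45 & u <= 1, 0.35 * 0.5 * (1 - cos(2 * pi * (u - 0.45) / 0.55)), 0)
    q <- e1 + e2
    q[!inside] <- 0
  }
  q[q < 0] <- 0
  q <- q * stroke_volume_ml / trapz_int(t, q)    # exact volume by construction
  structure(list(time_s = t, flow_ml_s = q,
                 heart_rate_bpm = heart_rate_bpm,
                 stroke_volume_ml = stroke_volume_ml,
                 filling_fraction = filling_fraction, shape = shape),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("Diastolic flow waveform (%s)\n", x$shape))
  cat(sprintf("  stroke volume : %.1f mL/beat\n", x$stroke_volume_ml))
  cat(sprintf("  heart rate    : %.0f bpm (cycle %.3f s)\n",
              x$heart_rate_bpm, 60 / x$heart_rate_bpm))
  cat(sprintf("  filling       : first %.0f%% of cycle, peak flow %.1f mL/s\n",
              100 * x$filling_fraction, max(x$flow_ml_s)))
  cat(sprintf("  samples       : %d\n", length(x$time_s)))
  invisible(x)
}

#' @export
plot.flow_waveform <- function(x, ...) {
  graphics::plot(x$time_s, x$flow_ml_s, type = "l",
                 xlab = "time (s)", ylab = "flow (mL/s)",
                 main = sprintf("%s waveform, %g mL/beat at %g bpm",
                                x$shape, x$stroke_volume_ml, x$heart_rate_bpm), ...)
  invisible(x)
}

# nominal-size -> anatomic orifice area (cm^2) for normal valves; per-valve
# areas are free parameters chosen so the normal-group mean is 2.9 cm^2 and,
# with the occluder multipliers below, the stenotic-group mean is ~1.2 cm^2
.aoa_table <- c(`27` = 2.4, `29` = 2.7, `31` = 3.1, `33` = 3.4)
.occluder_mult <- c(1, 0.55, 0.35)   # 0, 1, 2 occluders

#' Bioprosthetic valve model
#'
#' Describes one valve configuration of the flow loop: nominal size, anatomic
#' orifice area (AOA), degree of leaflet obstruction (0, 1 or 2 silicone
#' occluders), and the flow contraction coefficient Cc that maps the anatomic
#' area to the effective jet area, `A_eff = Cc * AOA`. Cc lies in [0.6, 1];
#' stenotic valves, driven by higher transvalvular gradients, use a Cc closer
#' to 1 than normal valves.
#'
#' @param size_mm Nominal valve size, one of 27, 29, 31, 33 (mm).
#' @param occluders Number of occluded leaflets, 0 (normal), 1 (mild stenosis)
#'   or 2 (severe stenosis).
#' @param aoa_cm2 Anatomic orifice area (cm^2). Defaults to a size-keyed table
#'   (27: 2.4, 29: 2.7, 31: 3.1, 33: 3.4) multiplied by 0.55 for one occluder
#'   and 0.35 for two.
#' @param cc Contraction coefficient in [0.6, 1]. Defaults to 0.62 for normal
#'   valves and 0.85 for stenotic ones.
#' @return An object of class `valve_model` with fields `size_mm`,
#'   `occluders`, `aoa_cm2`, `cc`.
#' @examples
#' valve_model(29)                 # normal 29 mm
#' valve_model(27, occluders = 2)  # severe stenosis
#' @export
valve_model <- function(size_mm, occluders = 0L, aoa_cm2 = NULL, cc = NULL) {
  if (!size_mm %in% c(27, 29, 31, 33))
    stop_invalid("'size_mm' must be one of 27, 29, 31, 33")
  if (!occluders %in% 0:2)
    stop_invalid("'occluders' must be 0, 1 or 2")
  if (is.null(aoa_cm2))
    aoa_cm2 <- unname(.aoa_table[as.character(size_mm)]) * .occluder_mult[occluders + 1L]
  check_scalar_pos(aoa_cm2, "aoa_cm2")
  if (is.null(cc)) cc <- if (occluders > 0) 0.85 else 0.62
  if (cc < 0.6 || cc > 1)
    stop_invalid("'cc' must lie in [0.6, 1]")
  structure(list(size_mm = size_mm, occluders = as.integer(occluders),
                 aoa_cm2 = aoa_cm2, cc = cc),
            class = "valve_model")
}

#' Effective jet area of a valve
#'
#' `A_eff = Cc * AOA` (cm^2): the cross-section actually occupied by flow at
#' the plane of maximal velocity (vena-contracta-like area).
#' @param valve A [valve_model()].
#' @return Effective area in cm^2.
#' @export
effective_area_cm2 <- function(valve) {
  stopifnot(inherits(valve, "valve_model"))
  valve$cc * valve$aoa_cm2
}

#' @export
print.valve_model <- function(x, ...) {
  lab <- c("normal", "single-occluder (mild stenosis)",
           "double-occluder (severe stenosis)")[x$occluders + 1L]
  cat(sprintf("Bioprosthetic mitral valve, %d mm, %s\n", x$size_mm, lab))
  cat(sprintf("  AOA  : %.2f cm^2\n", x$aoa_cm2))
  cat(sprintf("  Cc   : %.2f  ->  effective area %.2f cm^2\n",
              x$cc, effective_area_cm2(x)))
  invisible(x)
}

#' Ground-truth jet velocity trace
#'
#' Converts a volumetric flow waveform into the spatially uniform jet velocity
#' through the valve's effective area by conservation of volume flow:
#' `v(t) = Q(t) / A_eff` (mL/s over cm^2 gives cm/s), on the waveform's grid.
#'
#' @param waveform A [generate_diastolic_waveform()] result.
#' @param valve A [valve_model()].
#' @return A data frame with columns `time_s`, `v_cm_s`.
#' @export
true_velocity_trace <- function(waveform, valve) {
  stopifnot(inherits(waveform, "flow_waveform"), inherits(valve, "valve_model"))
  a_eff <- effective_area_cm2(valve)
  if (!is.finite(a_eff) || a_eff <= 0)
    stop_invalid("valve effective area must be positive")
  data.frame(time_s = waveform$time_s, v_cm_s = waveform$flow_ml_s / a_eff)
}

#' Write / read a flow waveform as 2-column CSV
#'
#' @param waveform A `flow_waveform`.
#' @param path Output CSV path (columns `time_s`, `flow_ml_s`).
#' @export
write_waveform_csv <- function(waveform, path) {
  stopifnot(inherits(waveform, "flow_waveform"))
  write.csv(data.frame(time_s = waveform$time_s, flow_ml_s = waveform$flow_ml_s),
            path, row.names = FALSE)
  invisible(path)
}
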