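#' Default 24-condition validation grid configuration
#'
#' Eight valve configurations (normal 27/29/31/33 mm; 27 and 29 mm each with
#' one or two occluders) crossed with stroke volumes of 70, 90 and 110 mL/beat
#' at 70 bpm. PC acquisitions use the default [acquisition_params()] with the
#' velocity-noise SD divided by `sqrt(pc_averages)` (8 signal averages);
#' Doppler traces average 5 consecutive beats.
#'
#' @return A named list with components `pump`, `valves`, `acquisition`,
#'   `doppler`, `pc_averages`, editable and serializable to YAML/JSON via
#'   [read_experiment_config()].
#' @export
default_grid_config <- function() {
  list(
    pump = list(stroke_volumes_ml = c(70, 90, 110), heart_rate_bpm = 70,
                shape = "half_sine", filling_fraction = 0.75, n_samples = 1024L),
    valves = list(
      list(size_mm = 27, occluders = 0L), list(size_mm = 29, occluders = 0L),
      list(size_mm = 31, occluders = 0L), list(size_mm = 33, occluders = 0L),
      list(size_mm = 27, occluders = 1L), list(size_mm = 27, occluders = 2L),
      list(size_mm = 29, occluders = 1L), list(size_mm = 29, occluders = 2L)),
    acquisition = list(),          # overrides for acquisition_params()
    doppler = list(n_beats = 5L, noise_sd_cm_s = 3, dt_ms = 2,
                   broadening = 0.05),
    pc_averages = 8
  )
}

#' Relative AOA-EOA area difference
#'
#' `100 (AOA - EOA) / AOA`, rounded to the nearest integer percent for
#' reporting.
#'
#' @param aoa_cm2 Anatomic orifice area (cm^2), > 0.
#' @param eoa_cm2 Effective orifice area (cm^2).
#' @return Integer percent.
#' @examples
#' relative_area_difference(2.9, 1.8)  # 38
#' relative_area_difference(1.2, 1.0)  # 17
#' @export
relative_area_difference <- function(aoa_cm2, eoa_cm2) {
  if (any(!is.finite(aoa_cm2)) || any(aoa_cm2 <= 0))
    stop_invalid("'aoa_cm2' must be positive")
  round(100 * (aoa_cm2 - eoa_cm2) / aoa_cm2)
}

# reference ("flow meter" / ground truth) summary for one condition
reference_summary <- function(waveform, valve) {
  v <- true_velocity_trace(waveform, valve)
  tr <- data.frame(time_s = v$time_s, v_cm_s = v$v_cm_s)
  g <- bernoulli_gradients(tr)
  valve_summary("reference",
                peak_velocity_cm_s = max(v$v_cm_s),
                tvi_cm = time_velocity_integral(tr),
                ffv_ml = waveform$stroke_volume_ml,
                eoa_cm2 = effective_area_cm2(valve),
                aoa_cm2 = valve$aoa_cm2,
                peak_gradient_mmhg = g$peak_gradient_mmhg,
                mean_gradient_mmhg = g$mean_gradient_mmhg)
}

#' Run the full validation grid
#'
#' For every valve x stroke-volume condition: generate the ground-truth
#' waveform, synthesize a PC series and a CW Doppler trace, run both analysis
#' pipelines plus the reference truth, and assemble (i) a long-format
#' per-condition table, (ii) normal/stenotic group means and SDs, and (iii)
#' cross-method agreement reports (FFV: PC vs reference; peak velocity, TVI,
#' EOA: PC vs Doppler; EOA additionally PC vs reference). Fully reproducible
#' for a fixed `seed`.
#'
#' @param config Configuration list, see [default_grid_config()].
#' @param seed Integer master seed; per-condition sub-seeds are drawn from it.
#' @param verbose Emit one log line per condition (default `FALSE`).
#' @return Object of class `pceoa_grid`: list with `conditions` (data frame,
#'   one row per condition x method), `group_summary`, `agreement` (named
#'   list of [agreement()] reports), `config`, `seed`.
#' @export
run_grid <- function(config = default_grid_config(), seed = 1L,
                     verbose = FALSE) {
  if (is.null(config$valves) || length(config$valves) == 0L ||
      is.null(config$pump$stroke_volumes_ml) ||
      length(config$pump$stroke_volumes_ml) == 0L)
    stop_invalid("config must list at least one valve and one stroke volume")
  pump <- config$pump
  dop <- config$doppler
  n_cond <- length(config$valves) * length(pump$stroke_volumes_ml)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_cond)
  acq_noise <- config$acquisition$noise_sd_cm_s %||%
    formals(acquisition_params)$noise_sd_cm_s
  eff_noise <- acq_noise / sqrt(config$pc_averages %||% 8)

  rows <- list(); ci <- 0L
  for (vdef in config$valves) {
    valve <- valve_model(vdef$size_mm, vdef$occluders %||% 0L,
                         aoa_cm2 = vdef$aoa_cm2, cc = vdef$cc)
    for (sv in pump$stroke_volumes_ml) {
      ci <- ci + 1L
      wf <- generate_diastolic_waveform(
        sv, pump$heart_rate_bpm,
        filling_fraction = pump$filling_fraction %||% 0.75,
        shape = pump$shape %||% "half_sine",
        n_samples = pump$n_samples %||% 1024L)
      acq_args <- config$acquisition
      acq_args$noise_sd_cm_s <- eff_noise
      acq_args$seed <- sub_seeds[2L * ci - 1L]
      params <- do.call(acquisition_params, acq_args)
      pc <- analyze_pc(synthesize_pc_series(wf, valve, params))
      cw <- synthesize_cw_trace(wf, valve,
                                noise_sd_cm_s = dop$noise_sd_cm_s %||% 3,
                                dt_ms = dop$dt_ms %||% 2,
                                seed = sub_seeds[2L * ci],
                                n_beats = dop$n_beats %||% 5L,
                                broadening = dop$broadening %||% 0.05)
      dopp <- analyze_cw(cw, reference_ffv_ml = sv,
                         n_beats = dop$n_beats %||% 5L)
      ref <- reference_summary(wf, valve)
      meta <- data.frame(condition = ci, size_mm = valve$size_mm,
                         occluders = valve$occluders,
                         group = if (valve$occluders > 0) "stenotic" else "normal",
                         stroke_volume_ml = sv,
                         aoa_true_cm2 = valve$aoa_cm2, cc = valve$cc)
      for (s in list(pc, dopp, ref))
        rows[[length(rows) + 1L]] <- cbind(meta, as.data.frame(unclass(s)))
      if (verbose)
        message(sprintf(
          "condition %02d | %d mm occ=%d sv=%g | PC EOA %.2f | Doppler EOA %.2f | true %.2f cm^2",
          ci, valve$size_mm, valve$occluders, sv, pc$eoa_cm2, dopp$eoa_cm2,
          effective_area_cm2(valve)))
    }
  }
  conditions <- do.call(rbind, rows)
  rownames(conditions) <- NULL

  metrics <- c("peak_velocity_cm_s", "tvi_cm", "ffv_ml", "eoa_cm2",
               "aoa_cm2", "peak_gradient_mmhg", "mean_gradient_mmhg")
  gs <- do.call(rbind, lapply(split(conditions,
                                    list(conditions$group, conditions$method)),
    function(d) {
      out <- data.frame(group = d$group[1], method = d$method[1],
                        n = nrow(d))
      for (m in metrics) {
        out[[paste0(m, "_mean")]] <- mean(d[[m]])
        out[[paste0(m, "_sd")]] <- sd(d[[m]])
      }
      out
    }))
  rownames(gs) <- NULL

  wide <- function(method, col)
    conditions[conditions$method == method, col][order(
      conditions[conditions$method == method, "condition"])]
  # degenerate sub-grids (too few conditions, or constant truth under a
  # single valve) cannot support every comparison; report what is estimable
  try_agreement <- function(x, y, label)
    tryCatch(agreement(x, y, label = label), error = function(e) NULL)
  agr <- list(
    ffv_pc_vs_reference = try_agreement(wide("reference", "ffv_ml"),
                                        wide("PC", "ffv_ml"),
                                        "FFV (mL/beat): PC vs reference"),
    peak_velocity_pc_vs_doppler = try_agreement(wide("Doppler", "peak_velocity_cm_s"),
                                                wide("PC", "peak_velocity_cm_s"),
                                                "Peak velocity (cm/s): PC vs Doppler"),
    tvi_pc_vs_doppler = try_agreement(wide("Doppler", "tvi_cm"),
                                      wide("PC", "tvi_cm"),
                                      "TVI (cm): PC vs Doppler"),
    eoa_pc_vs_doppler = try_agreement(wide("Doppler", "eoa_cm2"),
                                      wide("PC", "eoa_cm2"),
                                      "EOA (cm^2): PC vs Doppler"),
    eoa_pc_vs_reference = try_agreement(wide("reference", "eoa_cm2"),
                                        wide("PC", "eoa_cm2"),
                                        "EOA (cm^2): PC vs reference"))
  agr <- Filter(Negate(is.null), agr)

  structure(list(conditions = conditions, group_summary = gs,
                 agreement = agr, config = config, seed = seed),
            class = "pceoa_grid")
}

#' @export
print.pceoa_grid <- function(x, ...) {
  n_cond <- max(x$conditions$condition)
  cat(sprintf("Valve validation grid: %d conditions x %d methods (seed %d)\n",
              n_cond, length(unique(x$conditions$method)), x$seed))
  for (a in x$agreement)
    cat(sprintf("  %-38s r = %.3f, bias = %7.3f\n",
                a$label, a$pearson_r, a$bias))
  invisible(x)
}

#' @export
summary.pceoa_grid <- function(object, ...) {
  gs <- object$group_summary
  cat("Group means +/- SD (12 conditions per group)\n")
  fields <- list(c("ffv_ml", "FFV (mL/beat)"),
                 c("peak_velocity_cm_s", "Peak velocity (cm/s)"),
                 c("aoa_cm2", "AOA (cm^2)"),
                 c("mean_gradient_mmhg", "Mean gradient (mmHg)"),
                 c("eoa_cm2", "EOA (cm^2)"))
  for (f in fields) {
    cat(sprintf("%s\n", f[2]))
    for (i in seq_len(nrow(gs))) {
      mu <- gs[[paste0(f[1], "_mean")]][i]
      sdv <- gs[[paste0(f[1], "_sd")]][i]
      if (is.finite(mu))
        cat(sprintf("  %-9s %-9s %6.2f +/- %.2f\n",
                    gs$group[i], gs$method[i], mu, sdv))
    }
  }
  invisible(gs)
}

#' Write grid outputs as CSV
#'
#' Writes `conditions.csv`, `group_summary.csv` and `agreement.csv` into a
#' directory.
#'
#' @param grid A `pceoa_grid`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the output paths.
#' @export
write_grid_csv <- function(grid, outdir) {
  stopifnot(inherits(grid, "pceoa_grid"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(outdir, "conditions.csv")
  p2 <- file.path(outdir, "group_summary.csv")
  p3 <- file.path(outdir, "agreement.csv")
  write.csv(grid$conditions, p1, row.names = FALSE)
  write.csv(grid$group_summary, p2, row.names = FALSE)
  agr <- do.call(rbind, lapply(names(grid$agreement), function(nm) {
    a <- grid$agreement[[nm]]
    data.frame(comparison = nm, label = a$label, n = a$n,
               pearson_r = a$pearson_r, bias = a$bias,
               loa_low = a$loa_low, loa_high = a$loa_high, icc = a$icc,
               icc_model = a$icc_model)
  }))
  write.csv(agr, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
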