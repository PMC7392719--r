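test_that("noise-free instantaneous frames hit the true plateau velocity", {
  wf <- generate_diastolic_waveform(90, 70)
  valve <- valve_model(29)
  s <- synthesize_pc_series(wf, valve, dense_params(frame_interval_ms = 20))
  vtrue <- true_velocity_trace(wf, valve)
  expected <- approx(vtrue$time_s, vtrue$v_cm_s, s$frame_times_s, rule = 2)$y
  got <- apply(s$velocity_cm_s, 1, max)
  keep <- expected > 0.2 * max(expected)
  expect_lt(max(abs(got[keep] / expected[keep] - 1)), 0.01)
})

test_that("synthesis is bit-reproducible under a fixed seed", {
  wf <- generate_diastolic_waveform(70, 70)
  valve <- valve_model(31)
  p <- acquisition_params(seed = 77L)
  expect_identical(synthesize_pc_series(wf, valve, p)$velocity_cm_s,
                   synthesize_pc_series(wf, valve, p)$velocity_cm_s)
  cw1 <- synthesize_cw_trace(wf, valve, seed = 9L)
  cw2 <- synthesize_cw_trace(wf, valve, seed = 9L)
  expect_identical(cw1$envelope_cm_s, cw2$envelope_cm_s)
})

test_that("tighter orifices give faster jets at equal flow", {
  wf <- generate_diastolic_waveform(90, 70)
  p <- dense_params()
  v_norm <- max(synthesize_pc_series(wf, valve_model(27, 0), p)$velocity_cm_s)
  v_sten <- max(synthesize_pc_series(wf, valve_model(27, 2), p)$velocity_cm_s)
  expect_gt(v_sten, v_norm)
})

test_that("noise-free series carries the waveform's flow (faithfulness)", {
  wf <- generate_diastolic_waveform(90, 70)
  valve <- valve_model(29)
  p <- dense_params(frame_interval_ms = 48.9)
  s <- synthesize_pc_series(wf, valve, p)
  a_pix <- pixel_area_cm2(p)
  got <- apply(s$velocity_cm_s, 1, sum) * a_pix
  expected <- approx(wf$time_s, wf$flow_ml_s, s$frame_times_s, rule = 2)$y
  keep <- expected > 0.05 * max(expected)
  expect_lt(max(abs(got[keep] / expected[keep] - 1)), 0.02)
})

test_that("temporal averaging blunts the apparent peak velocity", {
  wf <- generate_diastolic_waveform(110, 70)
  valve <- valve_model(27, 2)
  sharp <- synthesize_pc_series(wf, valve, dense_params(frame_interval_ms = 48.9))
  blunt <- synthesize_pc_series(wf, valve,
    acquisition_params(noise_sd_cm_s = 0, temporal_window_ms = 48.9,
                       spatial_smooth = FALSE))
  vtrue <- max(true_velocity_trace(wf, valve)$v_cm_s)
  expect_lte(max(blunt$velocity_cm_s), vtrue + 1e-9)
  expect_lt(max(blunt$velocity_cm_s), max(sharp$velocity_cm_s))
})

test_that("velocities wrap beyond VENC only when aliasing is enabled", {
  wf <- generate_diastolic_waveform(90, 70)
  valve <- valve_model(27, 2)          # true peak ~330 cm/s
  vmax <- max(true_velocity_trace(wf, valve)$v_cm_s)
  low <- acquisition_params(noise_sd_cm_s = 0, temporal_window_ms = 0,
                            venc_cm_s = 150, aliasing = TRUE,
                            spatial_smooth = FALSE)
  s_low <- synthesize_pc_series(wf, valve, low)
  expect_true(all(abs(s_low$velocity_cm_s) <= 150 + 1e-9))
  expect_true(any(s_low$velocity_cm_s < -50))   # wrapped samples present
  high <- acquisition_params(noise_sd_cm_s = 0, temporal_window_ms = 0,
                             venc_cm_s = 1.2 * vmax, aliasing = TRUE,
                             spatial_smooth = FALSE)
  off <- acquisition_params(noise_sd_cm_s = 0, temporal_window_ms = 0,
                            venc_cm_s = 1.2 * vmax, aliasing = FALSE,
                            spatial_smooth = FALSE)
  expect_equal(synthesize_pc_series(wf, valve, high)$velocity_cm_s,
               synthesize_pc_series(wf, valve, off)$velocity_cm_s)
})

test_that("a jet larger than the field of view is a geometry error", {
  wf <- generate_diastolic_waveform(90, 70)
  p <- acquisition_params(grid_size = c(16L, 16L))
  expect_error(suppressWarnings(synthesize_pc_series(wf, valve_model(33), p)),
               "does not fit")
})

test_that("noise-free CW envelope without broadening is the true trace", {
  wf <- generate_diastolic_waveform(90, 70)
  valve <- valve_model(29)
  cw <- synthesize_cw_trace(wf, valve, noise_sd_cm_s = 0, dt_ms = 2,
                            n_beats = 1, broadening = 0)
  vtrue <- true_velocity_trace(wf, valve)
  # the trace is periodic: samples past the cycle end wrap to the next onset
  expected <- approx(vtrue$time_s, vtrue$v_cm_s,
                     cw$time_s %% cw$cycle_s, rule = 2)$y
  expect_equal(cw$envelope_cm_s, expected, tolerance = 1e-9)
  expect_error(synthesize_cw_trace(wf, valve, dt_ms = 10), "at most 5")
})

test_that("CW envelope noise has the configured SD (pre-clipping)", {
  wf <- generate_diastolic_waveform(90, 70)
  valve <- valve_model(29)
  cw <- synthesize_cw_trace(wf, valve, noise_sd_cm_s = 5, dt_ms = 2,
                            seed = 3L, n_beats = 40L, clip_negative = FALSE)
  zero_flow <- cw$time_s %% cw$cycle_s > 0.80 * cw$cycle_s
  expect_gt(sum(zero_flow), 2000)
  expect_equal(sd(cw$envelope_cm_s[zero_flow]), 5, tolerance = 0.05 * 5)
})

test_that("severe-stenosis envelope peaks at 110 mL/beat stay in the stenotic clinical range", {
  wf <- generate_diastolic_waveform(110, 70)
  for (size in c(27, 29)) {
    cw <- synthesize_cw_trace(wf, valve_model(size, 2), seed = 11L)
    pk <- max(cw$envelope_cm_s)
    expect_gte(pk, 151); expect_lte(pk, 418)
  }
})
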