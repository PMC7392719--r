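test_that("jet segmentation recovers the constructed jet core", {
  # build a ~80-pixel jet core: radius such that pi r^2 = 80 px
  nr <- 48; nc <- 48
  r_px <- sqrt(80 / pi)
  d2 <- outer((1:nr) - 24.5, (1:nc) - 24.5,
              function(a, b) sqrt(a^2 + b^2))
  fr <- 100 / (1 + exp(4 * (d2 - r_px)))       # sharp sigmoid edge ~1 px
  vel <- array(0, dim = c(3, nr, nc))
  for (k in 1:3) vel[k, , ] <- fr
  s <- manual_series(vel, pixel_spacing_mm = c(1, 1))
  roi <- segment_jet_roi(s, 0.5)
  expect_equal(sum(roi$mask[1, , ]), 80, tolerance = 8 / 80)
  expect_true(all(roi$mask[1, , ] == roi$mask[3, , ]))
})

test_that("segmentation keeps only the largest connected component", {
  vel <- array(0, dim = c(1, 32, 32))
  vel[1, 5:20, 5:20] <- 100        # 256-px blob
  vel[1, 26:29, 26:29] <- 100      # 16-px distractor, disjoint
  s <- manual_series(vel)
  roi <- segment_jet_roi(s, 0.5)
  expect_equal(sum(roi$mask[1, , ]), 256)
  expect_false(any(roi$mask[1, 26:29, 26:29]))
})

test_that("an all-zero series raises a no-jet error", {
  s <- manual_series(array(0, dim = c(2, 16, 16)))
  expect_error(segment_jet_roi(s), "no jet")
})

test_that("empty frames inherit the reference-frame mask", {
  vel <- array(0, dim = c(3, 32, 32))
  vel[2, 10:20, 10:20] <- 100      # only frame 2 has signal
  s <- manual_series(vel)
  roi <- segment_jet_roi(s, 0.5)
  expect_equal(roi$reference_frame, 2L)
  expect_true(all(roi$mask[1, , ] == roi$mask[2, , ]))
  expect_true(all(roi$mask[3, , ] == roi$mask[2, , ]))
})

test_that("instantaneous flow is velocity times pixel area over the ROI", {
  vel <- array(0, dim = c(2, 16, 16))
  vel[1, 8, 8] <- 100
  s <- manual_series(vel)                       # 1.2 x 0.9 mm pixels
  mask <- array(FALSE, dim = dim(vel)); mask[, 8, 8] <- TRUE
  fl <- instantaneous_flow(s, manual_roi(mask))
  expect_equal(fl$flow_ml_s[1], 100 * 0.0108)
  expect_equal(fl$flow_ml_s[2], 0)              # zero frame, same mask
  empty <- manual_roi(array(FALSE, dim = dim(vel)))
  expect_equal(instantaneous_flow(s, empty)$flow_ml_s, c(0, 0))
})

test_that("FFV integrates clipped flow; degenerate input errors", {
  tr <- data.frame(time_s = seq(0, 0.3, by = 0.05), flow_ml_s = 100)
  expect_equal(forward_flow_volume(tr), 30)
  tr2 <- tr; tr2$flow_ml_s <- c(-50, 100, 100, 100, 100, 100, -50)
  expect_equal(forward_flow_volume(tr2), 25)  # clipped ends enter as 0
  expect_error(forward_flow_volume(tr[1, , drop = FALSE]), "2 frames")
})

test_that("simulated FFV recovers the stroke volume (noise-free)", {
  wf <- generate_diastolic_waveform(90, 70)
  valve <- valve_model(29)
  s <- synthesize_pc_series(wf, valve,
    acquisition_params(noise_sd_cm_s = 0))     # 48.9 ms frames + averaging
  a <- analyze_pc(s)
  expect_equal(a$ffv_ml, 90, tolerance = 0.03)
})

test_that("peak-velocity trace takes the ROI maximum (or percentile)", {
  vel <- array(0, dim = c(2, 16, 16))
  vel[1, 6:10, 6:10] <- 120; vel[1, 8, 8] <- 150
  s <- manual_series(vel)
  mask <- array(FALSE, dim = dim(vel)); mask[, 6:10, 6:10] <- TRUE
  tr <- peak_velocity_trace(s, manual_roi(mask))
  expect_equal(tr$v_cm_s, c(150, 0))
  tr50 <- peak_velocity_trace(s, manual_roi(mask), percentile = 50)
  expect_equal(tr50$v_cm_s[1], 120)
  empty <- manual_roi(array(FALSE, dim = dim(vel)))
  expect_equal(peak_velocity_trace(s, empty)$v_cm_s, c(0, 0))
})

test_that("TVI closed forms: constant and half-sine traces", {
  tr <- data.frame(time_s = seq(0, 0.5, by = 0.005), v_cm_s = 100)
  expect_equal(time_velocity_integral(tr), 50, tolerance = 1e-9)
  t <- seq(0, 0.4, by = 0.0005)
  hs <- data.frame(time_s = t, v_cm_s = 150 * sin(pi * t / 0.4))
  expect_equal(time_velocity_integral(hs), 2 / pi * 150 * 0.4,
               tolerance = 0.005)
  expect_equal(time_velocity_integral(data.frame(time_s = t, v_cm_s = 0)), 0)
})

test_that("coarse sampling does not inflate the TVI (temporal blunting)", {
  wf <- generate_diastolic_waveform(90, 70)
  valve <- valve_model(29)
  vtrue <- true_velocity_trace(wf, valve)
  dense_tvi <- time_velocity_integral(
    data.frame(time_s = vtrue$time_s, v_cm_s = vtrue$v_cm_s))
  s <- synthesize_pc_series(wf, valve, acquisition_params(noise_sd_cm_s = 0))
  coarse_tvi <- analyze_pc(s)$tvi_cm
  expect_lte(coarse_tvi, dense_tvi * 1.02)
})

test_that("EOA arithmetic and domain errors", {
  expect_equal(pc_eoa(90, 60), 1.5)
  expect_equal(pc_eoa(0, 50), 0)
  expect_error(pc_eoa(90, 0), "positive")
  expect_error(pc_eoa(90, -3), "positive")
})

test_that("EOA identity: noise-free dense acquisition returns Cc x AOA", {
  # the pipeline's central oracle, checked per shape on a stenotic and a
  # normal valve (the full 24-condition sweep lives in the acceptance suite)
  for (shape in c("half_sine", "e_wave")) {
    for (valve in list(valve_model(29), valve_model(27, 2))) {
      wf <- generate_diastolic_waveform(90, 70, shape = shape)
      s <- synthesize_pc_series(wf, valve, dense_params())
      a <- analyze_pc(s)
      expect_equal(a$eoa_cm2, effective_area_cm2(valve), tolerance = 0.005)
    }
  }
})

test_that("planimetry counts jet-base pixels at the peak-flow frame", {
  nr <- 64; nc <- 64
  d2 <- outer((1:nr) - 32.5, (1:nc) - 32.5, function(a, b) sqrt(a^2 + b^2))
  disc <- ifelse(d2 <= sqrt(200 / pi), 100, 0)   # 200-pixel disc
  s <- manual_series(array(disc, dim = c(1, nr, nc)),
                     pixel_spacing_mm = c(1.2, 0.9))
  expect_equal(planimeter_aoa(s, 0.1), 200 * 0.0108, tolerance = 0.05)
  # exactly 100 pixels of a 0.01 cm^2 pixel grid
  vel <- array(0, dim = c(1, 32, 32)); vel[1, 11:20, 11:20] <- 80
  s2 <- manual_series(vel, pixel_spacing_mm = c(1, 1))
  expect_equal(planimeter_aoa(s2, 0.1), 1.00)
})

test_that("normal-valve planimetric AOA lands in the reported range", {
  aoas <- sapply(c(27, 29, 31, 33), function(sz) {
    wf <- generate_diastolic_waveform(90, 70)
    s <- synthesize_pc_series(wf, valve_model(sz),
                              acquisition_params(noise_sd_cm_s = 0))
    planimeter_aoa(s)
  })
  expect_gte(mean(aoas), 2.4)
  expect_lte(mean(aoas), 3.4)
})

test_that("simplified Bernoulli gradients follow 4 v^2", {
  t <- seq(0, 0.4, by = 0.002)
  tr <- data.frame(time_s = t, v_cm_s = 282 * sin(pi * t / 0.4))
  g <- bernoulli_gradients(tr)
  expect_equal(g$peak_gradient_mmhg, 4 * 2.82^2, tolerance = 1e-9)
  expect_lt(g$mean_gradient_mmhg, g$peak_gradient_mmhg)
  const <- data.frame(time_s = c(0, 0.2, 0.4), v_cm_s = 200)
  gc <- bernoulli_gradients(const)
  expect_equal(gc$peak_gradient_mmhg, 16)
  expect_equal(gc$mean_gradient_mmhg, 16)
  low <- data.frame(time_s = c(0, 0.2, 0.4), v_cm_s = 100)
  expect_equal(bernoulli_gradients(low)$peak_gradient_mmhg, 4)
})

test_that("FFV and TVI are linear in a global velocity scaling", {
  wf <- generate_diastolic_waveform(90, 70)
  valve <- valve_model(31)
  s <- synthesize_pc_series(wf, valve, dense_params(frame_interval_ms = 48.9))
  s2 <- s; s2$velocity_cm_s <- 2 * s$velocity_cm_s
  a1 <- analyze_pc(s); a2 <- analyze_pc(s2)
  expect_equal(a2$ffv_ml / a1$ffv_ml, 2, tolerance = 1e-9)
  expect_equal(a2$tvi_cm / a1$tvi_cm, 2, tolerance = 1e-9)
  expect_equal(a2$eoa_cm2, a1$eoa_cm2, tolerance = 1e-9)
})

test_that("AOA exceeds EOA and the gap shrinks as Cc approaches 1", {
  wf <- generate_diastolic_waveform(90, 70)
  gaps <- sapply(c(0.62, 0.75, 0.9), function(cc) {
    valve <- valve_model(29, cc = cc)
    a <- analyze_pc(synthesize_pc_series(wf, valve,
                                         acquisition_params(noise_sd_cm_s = 0)))
    expect_gte(a$aoa_cm2, a$eoa_cm2)
    (a$aoa_cm2 - a$eoa_cm2) / a$aoa_cm2
  })
  expect_true(all(diff(gaps) < 0))
})

test_that("valve_summary enforces its invariants", {
  expect_error(valve_summary("PC", -1, 10, 90, 1.5), "non-negative")
  expect_error(valve_summary("PC", 100, 10, 90, 1.5,
                             peak_gradient_mmhg = 3, mean_gradient_mmhg = 5),
               "peak gradient")
  s <- valve_summary("Doppler", 148, 50, 90, 1.8,
                     peak_gradient_mmhg = 8.8, mean_gradient_mmhg = 4)
  expect_s3_class(s, "valve_summary")
  expect_equal(s$eoa_cm2, s$ffv_ml / s$tvi_cm)
})
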