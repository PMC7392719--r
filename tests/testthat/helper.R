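# Shared fixture builders. Everything is generated in code; no data files.

# quiet acquisition: no noise, instantaneous sampling, dense frames
dense_params <- function(frame_interval_ms = 5, ...) {
  acquisition_params(noise_sd_cm_s = 0, temporal_window_ms = 0,
                     frame_interval_ms = frame_interval_ms, ...)
}

# hand-built pc_series from a velocity array (frames x rows x cols)
manual_series <- function(vel, pixel_spacing_mm = c(1.2, 0.9),
                          frame_interval_ms = 48.9) {
  d <- dim(vel)
  structure(list(
    velocity_cm_s = vel,
    frame_times_s = (seq_len(d[1]) - 0.5) * frame_interval_ms / 1000,
    params = acquisition_params(pixel_spacing_mm = pixel_spacing_mm,
                                frame_interval_ms = frame_interval_ms,
                                grid_size = d[2:3], noise_sd_cm_s = 0,
                                spatial_smooth = FALSE)),
    class = "pc_series")
}

manual_roi <- function(mask) {
  structure(list(mask = mask, source = "manual"), class = "roi_mask_series")
}

# the default validation grid is reused by several test files; computed once
cached_default_grid <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- run_grid(seed = 1)
    g
  }
})

# independent mean-squares oracle for the ICC forms, via stats::aov
icc_oracle <- function(ratings, model) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.vector(ratings),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  if (model == "one_way_single") {
    tab <- summary(stats::aov(y ~ subject, data = df))[[1]]
    msb <- tab["subject", "Mean Sq"]
    msw <- tab["Residuals", "Mean Sq"]
    (msb - msw) / (msb + (k - 1) * msw)
  } else {
    tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
    msr <- tab["subject", "Mean Sq"]
    msc <- tab["rater", "Mean Sq"]
    mse <- tab["Residuals", "Mean Sq"]
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
}
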