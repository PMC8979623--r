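test_that("load_capture reads grayscale and colour images with Rec.709 luminance", {
  f <- write_gray_png(matrix(1, 50, 100))
  cap <- load_capture(f, "pressure")
  expect_s3_class(cap, "pvz_capture")
  expect_equal(cap$width, 100)
  expect_equal(cap$height, 50)
  expect_true(all(cap$pixels == 1))

  # pure-red trace on black: grayscale value must be red's luminance weight
  rgb <- array(0, dim = c(20, 30, 3))
  rgb[10, , 1] <- 1
  f2 <- tempfile(fileext = ".png")
  png::writePNG(rgb, f2)
  cap2 <- load_capture(f2, "pressure")
  lum <- 0.2126 * 1 + 0.7152 * 0 + 0.0722 * 0  # independent computation
  expect_equal(cap2$pixels[10, 15], lum, tolerance = 1e-3)
  expect_true(all(cap2$pixels[-10, ] == 0))

  # JPEG round trip keeps dimensions and range
  f3 <- tempfile(fileext = ".jpg")
  jpeg::writeJPEG(matrix(0.5, 40, 60), f3)
  cap3 <- load_capture(f3, "doppler")
  expect_equal(c(cap3$height, cap3$width), c(40, 60))
  expect_true(all(cap3$pixels >= 0 & cap3$pixels <= 1))
})

test_that("load_capture rejects missing, empty and undecodable files", {
  expect_error(load_capture(tempfile(), "pressure"), class = "pvz_input_error")
  f <- tempfile(fileext = ".png")
  file.create(f)
  expect_error(load_capture(f, "pressure"), class = "pvz_input_error")
  writeLines("not an image", f)
  expect_error(load_capture(f, "pressure"), class = "pvz_input_error")
})

test_that("region_spec validates geometry and doppler fields", {
  expect_error(region_spec(10, 0, 10, 5, "line_trace"),
               class = "pvz_config_error")
  expect_error(region_spec(0, 0, 5, 5, "doppler_envelope",
                           envelope_direction = "above_baseline"),
               class = "pvz_config_error")  # baseline_row required
  expect_error(region_spec(0, 0, 5, 5, "doppler_envelope",
                           envelope_direction = "above_baseline",
                           baseline_row = 7),
               class = "pvz_config_error")  # baseline outside rectangle
  r <- region_spec(0, 10, 100, 60, "doppler_envelope",
                   envelope_direction = "above_baseline", baseline_row = 55)
  expect_equal(r$baseline_row, 55L)
})

test_that("line-trace detection finds constant and rendered sine paths", {
  # horizontal 1-px line at row 20 on black
  m <- matrix(0, 50, 80)
  m[21, ] <- 1
  cap <- structure(list(pixels = m, width = 80, height = 50,
                        source_path = "", capture_kind = "pressure"),
                   class = "pvz_capture")
  tr <- detect_line_trace(cap, region_spec(0, 0, 80, 50, "line_trace"))
  expect_equal(tr$columns, 0:79)
  expect_equal(tr$rows, rep(20, 80))

  # rendered sine of known pixel path (renderer stores the truth)
  sig <- calibrated_signal(10 + 5 * sin(2 * pi * 1.3 * seq(0, 4, by = 1e-3)),
                           1000, unit = "mmHg")
  ecg <- simulate_ecg(60, 4)$ecg
  rnd <- render_capture(sig, ecg, render_style(), "pressure_trace", seed = 3)
  det <- detect_line_trace(rnd$capture, rnd$regions$waveform)
  err <- abs(det$rows - rnd$truth$waveform_rows)
  expect_lt(max(err, na.rm = TRUE), 1.0)

  # all-black region
  expect_error(
    detect_line_trace(cap, region_spec(0, 30, 80, 50, "line_trace")),
    class = "pvz_detection_error"
  )
})

test_that("line-trace detection is invariant to global intensity scaling", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(0, 60, 100)
    path <- sample(5:54, 100, replace = TRUE)
    m[cbind(path + 1, 1:100)] <- 1
    cap <- structure(list(pixels = m, width = 100, height = 60,
                          source_path = "", capture_kind = "pressure"),
                     class = "pvz_capture")
    reg <- region_spec(0, 0, 100, 60, "line_trace")
    base <- detect_line_trace(cap, reg)
    for (c_scale in c(0.55, 0.8, 1.0)) {
      cap2 <- cap
      cap2$pixels <- cap$pixels * c_scale
      scaled <- detect_line_trace(cap2, reg)
      expect_lt(max(abs(scaled$rows - base$rows)), 0.1)
    }
  }
})

test_that("doppler envelope tracing follows the maximum-velocity edge", {
  # clean filled band of known envelope
  v <- calibrated_signal(pmax(0, 60 * sin(2 * pi * seq(0, 4, by = 1e-3) / 0.8)),
                         1000, unit = "cm/s")
  ecg <- simulate_ecg(75, 4)$ecg
  st <- render_style(speckle_density = 0)
  rnd <- render_capture(v, ecg, st, "doppler_spectrogram", seed = 5)
  det <- detect_doppler_envelope(rnd$capture, rnd$regions$waveform)
  expect_lt(max(abs(det$rows - rnd$truth$waveform_rows), na.rm = TRUE), 1.0 + 1e-9)

  # 10% speckle: outermost-edge + median-5 stays within 2 px
  st2 <- render_style(speckle_density = 0.1)
  for (seed in 1:5) {
    rnd2 <- render_capture(v, ecg, st2, "doppler_spectrogram", seed = seed)
    det2 <- detect_doppler_envelope(rnd2$capture, rnd2$regions$waveform)
    expect_lt(max(abs(det2$rows - rnd2$truth$waveform_rows), na.rm = TRUE),
              2.0 + 1e-9)
  }

  # uniform zero region
  dark <- structure(list(pixels = matrix(0, 60, 50), width = 50, height = 60,
                         source_path = "", capture_kind = "doppler"),
                    class = "pvz_capture")
  expect_error(
    detect_doppler_envelope(dark, region_spec(0, 0, 50, 60, "doppler_envelope",
                                              envelope_direction = "above_baseline",
                                              baseline_row = 55)),
    class = "pvz_detection_error"
  )
})

test_that("fill_gaps interpolates interior gaps and trims edges", {
  tr <- structure(list(columns = 0:2, rows = c(10, NA, 20)),
                  class = "pvz_trace")
  expect_equal(fill_gaps(tr)$rows, c(10, 15, 20))

  full <- structure(list(columns = 0:3, rows = c(1, 2, 3, 4)),
                    class = "pvz_trace")
  expect_equal(fill_gaps(full), full)

  edge <- structure(list(columns = 0:4, rows = c(NA, 5, NA, 7, NA)),
                    class = "pvz_trace")
  out <- fill_gaps(edge)
  expect_equal(out$columns, 1:3)
  expect_equal(out$rows, c(5, 6, 7))

  lone <- structure(list(columns = 0:2, rows = c(NA, 5, NA)),
                    class = "pvz_trace")
  expect_error(fill_gaps(lone), class = "pvz_detection_error")
})

test_that("calibrate_trace applies the affine anchor maps", {
  cal <- axis_calibration(c(0, 100), c(0, 1), c(0, 200), c(100, 0), "mmHg")
  tr <- structure(list(columns = 50L, rows = 100), class = "pvz_trace")
  # calibrate_trace requires >= 1 column; use two for a valid signal later
  tr2 <- structure(list(columns = c(50L, 60L), rows = c(100, 100)),
                   class = "pvz_trace")
  s <- calibrate_trace(tr2, cal)
  expect_equal(s$times[1], 0.5)
  expect_equal(s$values[1], 50)
  expect_equal(s$unit, "mmHg")

  # identity-like map: 1 px = 1 s, 1 px = -1 unit from row 0
  cal2 <- axis_calibration(c(0, 1), c(0, 1), c(0, 1), c(0, -1), "a.u.")
  tr3 <- structure(list(columns = 0:3, rows = c(2, 5, 1, 0)),
                   class = "pvz_trace")
  s2 <- calibrate_trace(tr3, cal2)
  expect_equal(s2$values, -c(2, 5, 1, 0))

  expect_error(axis_calibration(c(5, 5), c(0, 1), c(0, 1), c(0, 1), "u"),
               class = "pvz_config_error")
})

test_that("calibration round-trips through its inverse within 1e-9", {
  cal <- axis_calibration(c(13, 977), c(0.2, 7.9), c(280, 22), c(5.5, 95.1),
                          "mmHg")
  true_t <- seq(0.5, 7.5, length.out = 200)
  true_v <- 40 + 20 * sin(true_t)
  cols <- (true_t - 0.2) / ((7.9 - 0.2) / (977 - 13)) + 13
  rows <- (true_v - 5.5) / ((95.1 - 5.5) / (22 - 280)) + 280
  tr <- structure(list(columns = cols, rows = rows), class = "pvz_trace")
  s <- calibrate_trace(tr, cal)
  expect_lt(max(abs(s$times - true_t)), 1e-9)
  expect_lt(max(abs(s$values - true_v)), 1e-9)
})

test_that("resample_uniform interpolates linearly and is idempotent", {
  s <- structure(list(times = c(0, 1), values = c(0, 10),
                      unit = "mmHg", label = ""), class = "pvz_sampled")
  out <- resample_uniform(s, 1000)
  expect_length(out$values, 1001)
  expect_equal(out$values[501], 5.0)

  # already-uniform signal unchanged at shared grid points
  u <- calibrated_signal(sin(1:100), rate = 1000, unit = "x")
  again <- resample_uniform(u, 1000)
  expect_equal(again$values, u$values, tolerance = 1e-12)

  # re-resampling a ramp is the identity within 1e-9
  ramp <- structure(list(times = seq(0, 2, length.out = 21),
                         values = seq(0, 1, length.out = 21),
                         unit = "", label = ""), class = "pvz_sampled")
  r1 <- resample_uniform(ramp, 1000)
  r2 <- resample_uniform(r1, 1000)
  expect_lt(max(abs(r1$values - r2$values)), 1e-9)

  # no overshoot on a monotone segment
  mono <- structure(list(times = c(0, 0.3, 0.35, 1), values = c(0, 1, 5, 8),
                         unit = "", label = ""), class = "pvz_sampled")
  rm_ <- resample_uniform(mono, 500)
  expect_gte(min(rm_$values), 0)
  expect_lte(max(rm_$values), 8)
  expect_true(all(diff(rm_$values) >= -1e-12))

  bad <- structure(list(times = c(0, 1, 0.5), values = 1:3,
                        unit = "", label = ""), class = "pvz_sampled")
  expect_error(resample_uniform(bad), class = "pvz_data_error")
})

test_that("digitize-calibrate-resample round trip recovers rendered signals", {
  # property over several renderer seeds: RMS error at most the physical
  # size of 1.5 pixels under the stored calibration
  for (seed in 1:6) {
    set.seed(seed)
    hr <- stats::runif(1, 55, 100)
    sim <- simulate_flow(hr, stats::runif(1, 45, 95), 6, jitter = 0.03,
                         seed = seed)
    wk <- windkessel_params(0.05, 0.9, 3)
    pres <- apply_windkessel(sim$flow, wk)
    ecg <- simulate_ecg(hr, 6, r_times = sim$r_times)$ecg
    rnd <- render_capture(pres, ecg, render_style(), "pressure_trace",
                          seed = seed)
    det <- detect_line_trace(rnd$capture, rnd$regions$waveform)
    sig <- resample_uniform(
      calibrate_trace(fill_gaps(det), rnd$calibrations$waveform), 1000)
    t_sig <- sig$t0 + (seq_along(sig$values) - 1) / sig$rate
    t_true <- pres$t0 + (seq_along(pres$values) - 1) / pres$rate
    truth <- stats::approx(t_true, pres$values, xout = t_sig)$y
    px_size <- abs(rnd$calibrations$waveform$y_slope)
    rms <- sqrt(mean((sig$values - truth)^2))
    expect_lt(rms, 1.5 * px_size)
  }
})
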