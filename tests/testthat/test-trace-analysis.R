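test_that("moving_average: identity, constancy and impulse response", {
  x <- c(2, 2, 2, 2, 2)
  expect_identical(moving_average(x, 1), x)
  expect_equal(moving_average(x, 3), x)
  # unit impulse, window 7: interior plateau of 1/7 over the 7 centred samples
  imp <- c(rep(0, 10), 1, rep(0, 10))
  sm <- moving_average(imp, 7)
  expect_equal(sm[8:14], rep(1 / 7, 7))
  expect_equal(sm[7], 0)
  expect_equal(sum(sm > 0), 7)
  # even windows are accepted (the long background smoother uses 100)
  expect_equal(mean(moving_average(imp, 4)), mean(imp), tolerance = 0.05)
})

test_that("subtract_background removes constant and slow components", {
  roi <- c(10, 12, 14, 16, 18)
  expect_equal(subtract_background(roi, rep(0, 5), 3), roi)
  expect_equal(subtract_background(roi, rep(4, 5), 3), roi - 4)
  expect_equal(max(abs(subtract_background(roi, roi, 1))), 0)
  expect_error(subtract_background(roi, 1:4), "equal length")
})

test_that("detrend_polynomial removes fitted trend but preserves excluded pulses", {
  # exact polynomial removal
  x <- seq_len(200)
  y <- 3 + 0.05 * x - 2e-4 * x^2
  expect_lt(max(abs(detrend_polynomial(y, 2))), 1e-8)
  # ramp + excluded square pulse: ramp removed, pulse preserved
  pulse <- rep(0, 200)
  pulse[80:120] <- 5
  y2 <- 1 + 0.1 * x + pulse
  out <- detrend_polynomial(y2, 1, exclude_windows = list(c(80, 120)))
  expect_equal(out[100], 5, tolerance = 1e-8)
  expect_lt(max(abs(out[c(1:79, 121:200)])), 1e-8)
  expect_equal(mean(out[c(1:79, 121:200)]), 0, tolerance = 1e-10)
  # order 0 is mean subtraction of the non-excluded samples
  out0 <- detrend_polynomial(y2, 0, exclude_windows = list(c(80, 120)))
  expect_equal(out0[1], y2[1] - mean(y2[c(1:79, 121:200)]))
  # underdetermined fit is refused
  expect_error(detrend_polynomial(y2[1:8], 9), "underdetermined")
})

test_that("dff_event handles mean and extremum modes", {
  flat <- rep(100, 50)
  expect_equal(dff_event(flat, c(1, 20), c(30, 50), "mean"), 0)
  expect_equal(dff_event(flat, c(1, 20), c(30, 50), "extremum"), 0)
  y <- c(rep(100, 20), rep(0, 9), rep(101, 21))
  expect_equal(dff_event(y, c(1, 20), c(30, 50), "mean"), 0.01)
  y2 <- c(rep(100, 20), rep(100, 10), 97, 100, rep(100, 18))
  expect_equal(dff_event(y2, c(1, 20), c(30, 50), "extremum"), -0.03)
  # extremum picks the larger absolute deviation
  y3 <- c(rep(100, 20), rep(100, 10), 97, 102, rep(100, 18))
  expect_equal(dff_event(y3, c(1, 20), c(30, 50), "extremum"), -0.03)
  expect_error(dff_event(rep(0, 50), c(1, 20), c(30, 50)), "zero baseline")
  expect_error(dff_event(y, c(1, 30), c(30, 50)), "disjoint")
})

test_that("average_epochs averages stimulus and preceding baseline segments", {
  seg <- c(1, 2, 3, 4)
  trace <- c(rep(0, 4), seg, rep(0, 4), seg, rep(0, 4), seg)
  w <- list(c(5, 8), c(13, 16), c(21, 24))
  avg <- average_epochs(trace, w)
  expect_equal(avg$stimulus, seg)
  expect_equal(avg$baseline, rep(0, 4))
  # single epoch passthrough
  one <- average_epochs(trace, w, n_epochs = 1)
  expect_equal(one$stimulus, seg)
  # unequal epochs are refused
  expect_error(average_epochs(trace, list(c(5, 8), c(13, 17))), "same length")
  # zero-mean noise averages down roughly n-fold
  set.seed(11)
  n_rep <- 400
  len <- 50
  noise <- matrix(stats::rnorm(n_rep * len * 5), ncol = 5)
  var_single <- stats::var(noise[, 1])
  var_avg <- stats::var(rowMeans(noise))
  expect_equal(var_avg / var_single, 1 / 5, tolerance = 0.25)
})

test_that("in-vivo neuropil correction cancels shared contamination", {
  # flat background reduces to the plain mean-mode dF/F0
  roi <- c(rep(100, 25), rep(102, 25))
  bg <- rep(40, 50)
  expect_equal(in_vivo_dff(roi, bg, c(26, 50), c(1, 25)), 0.02)
  # shared additive step cancels exactly
  shared <- c(rep(0, 25), rep(1, 25))
  expect_equal(in_vivo_dff(roi + shared, bg + shared, c(26, 50), c(1, 25)),
               0.02)
  # roi step +2% plus shared +1% artefact on baseline 100 -> 0.02
  roi2 <- c(rep(100, 25), rep(100 + 2 + 1, 25))
  bg2 <- c(rep(40, 25), rep(41, 25))
  expect_equal(in_vivo_dff(roi2, bg2, c(26, 50), c(1, 25)), 0.02)
  expect_error(in_vivo_dff(roi, bg, c(26, 50), c(1, 20)), "equal duration")
})

test_that("calibration converts dF/F0 at ~5.42 mV per percent", {
  cal <- calibration()
  expect_equal(dff_to_voltage(0, cal), 0)
  expect_equal(abs(dff_to_voltage(0.01, cal)), 5.42005420054,
               tolerance = 1e-9)
  expect_equal(dff_to_voltage(-0.01, cal), -dff_to_voltage(0.01, cal))
  # fluorescence increase = hyperpolarization under the default convention
  expect_lt(dff_to_voltage(0.01, cal), 0)
  expect_error(calibration(0), "non-zero")
})

test_that("driving-force estimates are invariant to overall photon scaling", {
  sc <- synth_scenario(true_df = -7, tau_ms = 2, noise = FALSE)
  r <- render_recording(sc)
  rec <- r$recording
  est1 <- estimate_df_gabaa(rec)
  rec2 <- fluor_recording(rec$data$time, rec$data$roi * 3.7,
                          rec$data$background * 3.7,
                          rec$stimulus_windows, rec$frame_rate)
  est2 <- estimate_df_gabaa(rec2)
  expect_equal(est2$df_gabaa, est1$df_gabaa, tolerance = 1e-10)
})

test_that("noiseless round trip recovers the imposed driving force", {
  for (df in c(-15, -6, 0, 6, 15)) {
    sc <- synth_scenario(true_df = df, tau_ms = 2, noise = FALSE)
    est <- estimate_df_gabaa(render_recording(sc)$recording)
    expect_lt(abs(est$df_gabaa - df), 0.1)
    # sign conventions: measured shift is the negative of the driving force
    expect_equal(df_as_shift(est), -est$df_gabaa)
  }
})

test_that("extremum (puff) mode recovers a single-response deflection", {
  sc <- synth_scenario(true_df = -8, tau_ms = 2, noise = FALSE,
                       n_epochs = 1, first_onset_s = 3, epoch_duration_s = 1,
                       duration_s = 10, bleach_fraction_per_25s = 0.02)
  rec <- render_recording(sc)$recording
  rec$stimulus_windows$kind <- "agonist_puff"
  est <- estimate_df_gabaa(rec, mode = "extremum", response_s = 1)
  expect_equal(est$df_gabaa, -8, tolerance = 0.15)
})

test_that("in-vivo mode removes shared background transients", {
  sc <- synth_scenario(true_df = 5, tau_ms = 2, noise = FALSE, n_epochs = 1,
                       first_onset_s = 10, epoch_duration_s = 2,
                       duration_s = 16, bleach_fraction_per_25s = 0,
                       background_level = 0,
                       artefact = list(amplitude = 400, start = 10, end = 12))
  rec <- render_recording(sc)$recording
  est <- estimate_df_gabaa(rec, mode = "in_vivo")
  # the +400-count artefact hits stimulus but not flank on both traces and
  # cancels; without correction it would corrupt the estimate by >1 mV
  expect_equal(est$df_gabaa, 5, tolerance = 0.1)
  raw <- dff_event(rec$data$roi, c(201, 250), c(251, 300), "mean")
  expect_gt(abs(-dff_to_voltage(raw) - 5), 1)
})

test_that("tidy and glance summarise an estimate", {
  sc <- synth_scenario(true_df = -6, tau_ms = 2, noise = FALSE)
  est <- estimate_df_gabaa(render_recording(sc)$recording)
  td <- tidy(est)
  expect_named(td, c("dff", "delta_v", "df_gabaa", "mode"))
  expect_identical(glance(est), td)
})
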