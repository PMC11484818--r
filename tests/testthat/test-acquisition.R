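test_that("photon-budget chain reproduces the published numbers", {
  spec <- acquisition_spec()
  expect_equal(electrons_per_frame(spec), 36585.3658537, tolerance = 1e-8)
  expect_equal(electrons_per_frame(acquisition_spec(quantum_efficiency = 1)),
               30000)
  expect_equal(electrons_per_frame(acquisition_spec(well_depth = 60000)),
               2 * electrons_per_frame(spec))
  expect_equal(required_f0(10, 0.01), 1e6)
  expect_equal(required_f0(0, 0.01), 0)
  expect_equal(required_f0(40, 0.01), 16 * required_f0(10, 0.01))
  fr <- frames_required(1e6, electrons_per_frame(spec))
  expect_equal(fr$frames, 27.3333333, tolerance = 1e-6)
  expect_equal(fr$frames_ceiling, 28)
  expect_equal(frames_required(0, 100)$frames, 0)
  expect_equal(frames_required(1e6, 50)$frames,
               2 * frames_required(1e6, 100)$frames)
})

test_that("stimulation SNR matches the published 1 s and 2 s predictions", {
  expect_equal(snr_for_stimulation(acquisition_spec(stimulus_duration = 1)),
               9.6, tolerance = 0.1 / 9.6)
  expect_equal(snr_for_stimulation(acquisition_spec(stimulus_duration = 2)),
               13.5, tolerance = 0.1 / 13.5)
  expect_equal(snr_for_stimulation(acquisition_spec(target_dff = 1e-12)), 0,
               tolerance = 1e-6)
})

test_that("SNR chain is self-consistent and scales as sqrt(frames)", {
  spec <- acquisition_spec()
  epf <- electrons_per_frame(spec)
  f0 <- required_f0(spec$target_snr, spec$target_dff)
  n <- frames_required(f0, epf)$frames
  # collecting exactly those frames returns the target SNR
  back <- snr_for_stimulation(acquisition_spec(
    stimulus_duration = n / spec$frame_rate))
  expect_equal(back, spec$target_snr, tolerance = 1e-9)
  s1 <- snr_for_stimulation(acquisition_spec(stimulus_duration = 1))
  s4 <- snr_for_stimulation(acquisition_spec(stimulus_duration = 4))
  expect_equal(s4 / s1, 2, tolerance = 1e-12)
})

test_that("design_report chains all quantities", {
  rep <- design_report()
  expect_equal(rep$electrons_per_frame, 30000 / 0.82)
  expect_equal(rep$required_f0, 1e6)
  expect_equal(rep$frames_required_ceiling, 28)
  expect_equal(rep$expected_snr, 9.6, tolerance = 0.1 / 9.6)
})

test_that("shot-noise SD predictions scale correctly", {
  p1 <- predicted_df_sd(36585.37, 250, 250)
  # quadrupling the frame count halves the SD
  p4 <- predicted_df_sd(36585.37, 1000, 1000)
  expect_equal(p1$sd_mV / p4$sd_mV, 2, tolerance = 1e-12)
  # background photons only add variance
  pb <- predicted_df_sd(36585.37, 250, 250, background = 3000)
  expect_gt(pb$sd_mV, p1$sd_mV)
  expect_equal(p1$sd_dff, sqrt(2 / 250 / 36585.37), tolerance = 1e-12)
})

test_that("pipeline SD propagation reduces to the bound without detrending", {
  sc <- synth_scenario(true_df = 0, noise = FALSE, bleach_fraction_per_25s = 0,
                       background_level = 0)
  rec <- render_recording(sc)$recording
  # order-0 detrend barely perturbs the contrast: the propagated SD must sit
  # near the white shot-noise bound for 5 x 2 s epochs at 25 Hz
  got <- pipeline_df_sd(rec, detrend_order = 0, bg_smooth_window = 1)
  bound <- predicted_df_sd(36585.37, 250, 250)
  expect_equal(got$sd_mV, bound$sd_mV, tolerance = 0.1)
  # the published 9th-order detrend amplifies the estimator noise
  amp <- pipeline_df_sd(rec, detrend_order = 9, bg_smooth_window = 1)
  expect_gt(amp$sd_mV, 2 * bound$sd_mV)
})
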