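test_that("voltage generator: flat at zero driving force, plateau otherwise", {
  sc0 <- synth_scenario(true_df = 0)
  expect_equal(generate_vm_trace(sc0), rep(sc0$v_rest, 625))
  # negative driving force: depolarizing deflection of matching magnitude
  sc <- synth_scenario(true_df = -6, tau_ms = 2)
  vm <- generate_vm_trace(sc)
  tm <- (seq_along(vm) - 1) / sc$frame_rate
  during <- tm >= 3.5 & tm < 4.5   # second half of epoch 1: settled
  expect_equal(unique(round(vm[during], 6)), sc$v_rest + 6)
  # between epochs the trace returns to rest
  expect_equal(vm[tm > 6.5 & tm < 7.4], rep(sc$v_rest, sum(tm > 6.5 & tm < 7.4)),
               tolerance = 1e-6)
  # slow kinetics never overshoot
  sc_slow <- synth_scenario(true_df = 6, tau_ms = 500)
  vm_slow <- generate_vm_trace(sc_slow)
  expect_true(all(vm_slow >= sc$v_rest - 6 - 1e-9))
  expect_gt(min(vm_slow), sc$v_rest - 6 + 0.01)
})

test_that("seizure-like template superimposes on the voltage trace", {
  sc <- synth_scenario(true_df = 0,
                       sle = list(amplitude_mV = 25, start = 10, end = 20))
  vm <- generate_vm_trace(sc)
  tm <- (seq_along(vm) - 1) / sc$frame_rate
  expect_equal(unique(vm[tm >= 10 & tm < 20]), sc$v_rest + 25)
  expect_equal(unique(vm[tm < 10]), sc$v_rest)
  # and is detected by the SLE rule on a noisy version
  set.seed(3)
  ev <- detect_sle(vm + stats::rnorm(length(vm), 0, 0.5), sc$frame_rate,
                   baseline_window = c(0, 8))
  expect_equal(nrow(ev), 1)
})

test_that("fluorescence gain is linear with the stated sign convention", {
  sc <- synth_scenario(true_df = 0, bleach_fraction_per_25s = 0)
  expect_equal(vm_to_fluorescence(rep(sc$v_rest, 10), sc, 1:10 / 25),
               rep(sc$photons_per_frame, 10))
  # hyperpolarizing step increases fluorescence
  f_hyp <- vm_to_fluorescence(rep(sc$v_rest - 10, 1), sc, 0)
  expect_gt(f_hyp, sc$photons_per_frame)
  # -5.42 mV maps to +1% dF/F0 under the bundled slope
  f <- vm_to_fluorescence(rep(sc$v_rest - 5.42005420054, 1), sc, 0)
  expect_equal(f / sc$photons_per_frame - 1, 0.01, tolerance = 1e-9)
  bad <- synth_scenario(true_df = 0)
  expect_error(vm_to_fluorescence(rep(sc$v_rest + 1e5, 1), bad, 0),
               "non-positive")
})

test_that("shot noise is Poisson and seeded", {
  expect_equal(add_shot_noise(rep(0, 100), seed = 1), rep(0, 100))
  draws <- add_shot_noise(rep(1e6, 1e4), seed = 42)
  # CLT bound on the mean: 3 standard errors
  expect_lt(abs(mean(draws) - 1e6), 3 * sqrt(1e6 / 1e4))
  # variance tracks the mean (Poisson), within 5%
  expect_equal(stats::var(draws) / 1e6, 1, tolerance = 0.05)
  expect_identical(add_shot_noise(rep(50, 10), seed = 7),
                   add_shot_noise(rep(50, 10), seed = 7))
  expect_error(add_shot_noise(c(-1, 2)), ">= 0")
})

test_that("rendered recordings are deterministic and carry their manifest", {
  sc <- synth_scenario(true_df = -6)
  r1 <- render_recording(sc, seed = 5)
  r2 <- render_recording(sc, seed = 5)
  expect_identical(r1$recording$data, r2$recording$data)
  r3 <- render_recording(sc, seed = 6)
  expect_false(identical(r1$recording$data$roi, r3$recording$data$roi))
  # manifest: per-epoch truths and lossless serialization round trip
  m <- r1$manifest
  expect_equal(nrow(m$per_epoch), 5)
  expect_equal(m$per_epoch$true_delta_v[3], 6, tolerance = 0.2)  # tau bias
  expect_equal(m$seed, 5)
  path <- withr::local_tempfile(fileext = ".json")
  m$per_epoch <- as.data.frame(m$per_epoch)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$scenario$true_df, -6)
  expect_equal(back$per_epoch$true_dff, m$per_epoch$true_dff,
               tolerance = 1e-12)
})

test_that("mechanistic mode drives the plateau toward the model's E_GABAA", {
  sc <- synth_scenario(true_df = NA, mechanistic = TRUE, n_epochs = 2,
                       epoch_duration_s = 2, duration_s = 15,
                       opto_g_nS = 10)
  vm <- generate_vm_trace(sc)
  tm <- (seq_along(vm) - 1) / sc$frame_rate
  ss <- default_ss()
  e_gabaa <- gabaa_reversal(ss$Cl_i, 110, ss$HCO3_i, 31)
  plateau <- vm[tm >= 4.2 & tm < 4.5]   # end of epoch 1
  # the conductance pulls Vm more than half-way from rest toward the reversal
  # (residual leak current and pulse-driven chloride loading keep a gap)
  expect_lt(abs(mean(plateau) - e_gabaa), 0.5 * abs(ss$Vm - e_gabaa))
  expect_lt(mean(plateau), ss$Vm - 2)
  expect_equal(vm[1], ss$Vm, tolerance = 0.01)
})

test_that("scenario validation catches impossible schedules", {
  expect_error(synth_scenario(n_epochs = 10, epoch_period_s = 5,
                              duration_s = 25), "schedule")
  expect_error(synth_scenario(first_onset_s = 0.5, epoch_duration_s = 2),
               "baseline")
})
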