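p0 <- model_params()

test_that("compartment geometry follows the cylinder parameters", {
  g <- compartment_geometry(p0)
  expect_equal(g$surface_area_m2, 2 * pi * 5e-6 * 25e-6)
  expect_equal(g$volume_pL, pi * 5e-6^2 * 25e-6 * 1e15)  # ~1.96 pL
  expect_error(compartment_geometry(model_params(radius_um = 1e-12,
                                                 length_um = 1e-12)),
               NA)  # tiny but positive is fine
})

test_that("membrane_voltage is zero for electroneutral interiors and linear", {
  st <- ion_state(Na_i = 10, K_i = 100, Cl_i = 10, HCO3_i = 15, X_i = 100,
                  Vm = 0, w = 1.96, t = 0)
  # choose X charge so the interior is exactly neutral: z = -(10+100-10-15)/100
  p <- model_params(z_i = -0.85)
  st_neutral <- ion_state(10, 100, 10, 15, (10 + 100 - 10 - 15) / 0.85, 0, 1.96)
  expect_equal(membrane_voltage(st_neutral, p), 0, tolerance = 1e-9)
  # doubling the net charge doubles Vm
  st1 <- ion_state(10 + 1, 100, 10, 15, (10 + 100 - 10 - 15) / 0.85, 0, 1.96)
  st2 <- ion_state(10 + 2, 100, 10, 15, (10 + 100 - 10 - 15) / 0.85, 0, 1.96)
  expect_equal(membrane_voltage(st2, p), 2 * membrane_voltage(st1, p),
               tolerance = 1e-9)
})

test_that("steady state reproduces the published default column", {
  ss <- default_ss()
  expect_equal(ss$Vm, -67.2, tolerance = 1.5 / 67.2)
  expect_equal(membrane_voltage(ss, p0), -67.2, tolerance = 1.5 / 67.2)
  expect_equal(ss$Cl_i, 5.3, tolerance = 0.3 / 5.3)
  expect_equal(ss$K_i, 122.6, tolerance = 1.5 / 122.6)
  expect_equal(ss$HCO3_i, 9.7, tolerance = 0.1 / 9.7)
  expect_true(attr(ss, "converged"))
  # osmotic balance at steady state
  ps <- optodf:::params_si(p0)
  pi_i <- ss$Na_i + ss$K_i + ss$Cl_i + ss$HCO3_i + ss$X_i
  expect_lt(abs(pi_i - ps$Pi_o), 1e-3)
})

test_that("pump, KCC2 and zero-conductance limits of the fluxes", {
  ss <- default_ss()
  # all pathways off: every flux vanishes
  p_off <- model_params(g_Na = 0, g_K = 0, g_Cl = 0, g_HCO3 = 0, g_KCC2 = 0,
                        P_pump = 0, Kf = 1e-12, Kr = 1e-12)
  fl <- transmembrane_fluxes(ss, p_off)
  expect_equal(unname(fl$flux), rep(0, 5), tolerance = 1e-25)
  expect_equal(fl$current_A, 0, tolerance = 1e-20)
  # cubic pump law: printed-value check in the published unit system
  st <- ion_state(Na_i = 15, K_i = 122.6, Cl_i = 5.3, HCO3_i = 9.7,
                  X_i = 144.4, Vm = -67.2, w = 1.96)
  jp <- transmembrane_fluxes(st, p0)$Jp        # C/(m^2 s)
  expect_equal(jp / 1e2, 0.1 * (15 / 145)^3, tolerance = 1e-12)  # C/(dm^2 s)
  expect_equal(jp / 1e2, 1.10705645988e-4, tolerance = 1e-9)
  # KCC2 carries nothing when E_K = E_Cl: pick Cl_i so the gradients match
  cl_match <- 110 * 3.5 / 122.6
  st_eq <- ion_state(15, 122.6, cl_match, 9.7, 144.4, -67.2, 1.96)
  p_kcc2 <- model_params(g_Na = 0, g_K = 0, g_Cl = 0, g_HCO3 = 0,
                         P_pump = 0, Kf = 1e-12, Kr = 1e-12)
  fl2 <- transmembrane_fluxes(st_eq, p_kcc2)
  expect_equal(unname(fl2$flux[c("K", "Cl")]), c(0, 0), tolerance = 1e-22)
})

test_that("flux bookkeeping: charge rate equals minus the membrane current", {
  ps <- optodf:::params_si(p0)
  set.seed(7)
  for (i in 1:20) {
    st <- ion_state(Na_i = stats::runif(1, 5, 30),
                    K_i = stats::runif(1, 80, 150),
                    Cl_i = stats::runif(1, 2, 30),
                    HCO3_i = stats::runif(1, 2, 20),
                    X_i = stats::runif(1, 100, 160),
                    Vm = 0, w = stats::runif(1, 1.5, 2.5))
    fl <- transmembrane_fluxes(st, p0, g_gabaa_now = stats::runif(1, 0, 10))
    dq_dt <- fl$flux[["Na"]] + fl$flux[["K"]] - fl$flux[["Cl"]] -
      fl$flux[["HCO3"]]
    expect_equal(ps$F * dq_dt, -fl$current_A, tolerance = 1e-10)
  }
})

test_that("volume derivative follows the osmotic gradient", {
  ss <- default_ss()
  expect_equal(volume_derivative(ss, p0), 0, tolerance = 1e-6)
  # published default column sums to the bath osmolarity of 297 mM
  expect_equal(15 + 122.6 + 5.3 + 9.7 + 144.4, 297)
  swollen <- ion_state(ss$Na_i + 10, ss$K_i, ss$Cl_i, ss$HCO3_i, ss$X_i,
                       ss$Vm, ss$w)
  expect_gt(volume_derivative(swollen, p0), 0)
  p_no_water <- model_params(pw = 1e-30)
  expect_equal(volume_derivative(swollen, p_no_water), 0, tolerance = 1e-20)
})

test_that("fixed-step integrator: zero-flux identity and step-halving", {
  p_off <- model_params(g_Na = 0, g_K = 0, g_Cl = 0, g_HCO3 = 0, g_KCC2 = 0,
                        P_pump = 0, Kf = 1e-12, Kr = 1e-12, pw = 1e-30)
  st <- initial_state(p_off)
  st1 <- step_state(st, p_off, dt = 0.1)
  expect_equal(st1$t, 0.1)
  expect_equal(unlist(st1[c("Na_i", "K_i", "Cl_i", "HCO3_i", "X_i", "w")]),
               unlist(st[c("Na_i", "K_i", "Cl_i", "HCO3_i", "X_i", "w")]),
               tolerance = 1e-12)
  # two half-steps agree with one full step to the scheme's order
  st <- default_ss()
  st$Cl_i <- st$Cl_i + 2   # electroneutral KCl load: real dynamics, sane Vm
  st$K_i <- st$K_i + 2
  full <- step_state(st, p0, dt = 1e-3)
  half <- step_state(step_state(st, p0, dt = 5e-4), p0, dt = 5e-4)
  expect_equal(half$Cl_i, full$Cl_i, tolerance = 1e-9)
  expect_equal(half$Vm, full$Vm, tolerance = 1e-7)
})

test_that("adaptive and fixed-step integrators agree on a mixed protocol", {
  prot <- stim_protocol(
    param_ramp("g_KCC2", 20, 10, 2, 6),
    gaba_pulse(7, tau_ms = 250, g_max_nS = 2)
  )
  ss <- default_ss()
  t_out <- seq(0, 10, by = 0.5)
  a <- simulate_model(p0, prot, duration = 10, times = t_out, state0 = ss)
  b <- simulate_model(p0, prot, duration = 10, times = t_out, state0 = ss,
                      method = "rk4", dt = 1e-3)
  fa <- a$trajectory[nrow(a$trajectory), ]
  fb <- b$trajectory[nrow(b$trajectory), ]
  for (v in c("Na_i", "K_i", "Cl_i", "HCO3_i", "Vm")) {
    expect_equal(fb[[v]], fa[[v]], tolerance = 1e-6)
  }
})

test_that("a 60-min unperturbed run drifts less than 0.5% per concentration", {
  sim <- simulate_model(p0, duration = 3600, dt_out = 60)
  first <- sim$trajectory[1, ]
  last <- sim$trajectory[nrow(sim$trajectory), ]
  for (v in c("Na_i", "K_i", "Cl_i", "HCO3_i", "X_i")) {
    expect_lt(abs(last[[v]] - first[[v]]) / first[[v]], 0.005)
  }
  expect_true(all(diff(sim$trajectory$t) > 0))
})

test_that("voltage-clamped single-anion limit satisfies the Nernst relation", {
  # huge capacitance pins Vm ~ 0; with only the chloride leak active the
  # steady state must equilibrate chloride with the bath (E_Cl = Vm ~ 0)
  p <- model_params(Cm = 1, g_Na = 0, g_K = 0, g_HCO3 = 0, g_KCC2 = 0,
                    P_pump = 0, Kf = 1e-12, Kr = 1e-12, pw = 1e-30)
  st0 <- initial_state(p, Vm_target_mV = -30)
  sim <- simulate_model(p, duration = 25000, dt_out = 500, state0 = st0)
  fin <- sim$trajectory[nrow(sim$trajectory), ]
  # the huge capacitance pins Vm near its initial value (the accumulated
  # chloride charge moves it < 1 mV); chloride equilibrates to the Nernst
  # concentration at that voltage
  expect_lt(abs(fin$Vm - (-30)), 1)
  expect_equal(fin$Cl_i, 110 * exp(fin$Vm / 26.7266512847), tolerance = 1e-4)
  expect_equal(fin$E_Cl, fin$Vm, tolerance = 1e-4)
})

test_that("steady-state chloride rises monotonically as KCC2 is removed", {
  cl <- vapply(c(20, 10, 5, 0), function(g) {
    steady_state(model_params(g_KCC2 = g))$Cl_i
  }, numeric(1))
  expect_true(all(diff(cl) > 0))
  # full block: clearly above the default steady state
  expect_gt(cl[4], default_ss()$Cl_i + 3)
})

test_that("simulate_model validates protocol timing and stays deterministic", {
  expect_error(simulate_model(p0, stim_protocol(gaba_pulse(100)), duration = 50),
               "within")
  ss <- default_ss()
  s1 <- simulate_model(p0, stim_protocol(gaba_pulse(5)), duration = 10,
                       state0 = ss)
  s2 <- simulate_model(p0, stim_protocol(gaba_pulse(5)), duration = 10,
                       state0 = ss)
  expect_identical(s1$trajectory, s2$trajectory)
})

test_that("GABA pulse at rest hyperpolarizes toward E_GABAA", {
  ss <- default_ss()
  sim <- simulate_model(p0, stim_protocol(gaba_pulse(5)), duration = 15,
                        state0 = ss)
  tr <- sim$trajectory
  during <- tr[tr$t > 5 & tr$t < 7, ]
  expect_lt(min(during$Vm), ss$Vm - 2)          # hyperpolarizing deflection
  expect_gt(min(during$Vm), min(during$E_GABAA) - 1)  # bounded by reversal
  # driving force collapses while the conductance is open (shunt)
  df0 <- df_timecourse(sim, 4.99)
  df_peak <- df_timecourse(sim, 5 + 0.25)
  expect_lt(abs(df_peak), abs(df0))
})

test_that("df_timecourse interpolates and rejects out-of-range probes", {
  ss <- default_ss()
  sim <- simulate_model(p0, duration = 10, state0 = ss)
  expect_equal(df_timecourse(sim, 0), ss$Vm - gabaa_reversal(
    ss$Cl_i, 110, ss$HCO3_i, 31), tolerance = 1e-6)
  expect_equal(df_timecourse(sim, c(3, 3)), rep(df_timecourse(sim, 3), 2))
  expect_error(df_timecourse(sim, 11), "outside")
})
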