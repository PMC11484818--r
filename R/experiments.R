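# Scripted in-silico protocols probing what sets the GABA-A driving force:
# blocking the Cl- extruder KCC2 versus adding impermeant anionic charge.

measure_pulse <- function(traj, onset, span = 4) {
  pre <- traj[traj$t <= onset, ]
  base <- pre[nrow(pre), ]
  win <- traj[traj$t > onset & traj$t <= onset + span, ]
  dev <- win$Vm - base$Vm
  peak <- dev[which.max(abs(dev))]
  tibble::tibble(
    t_pulse = onset,
    Vm_baseline = base$Vm, E_GABAA_baseline = base$E_GABAA,
    E_Cl_baseline = base$E_Cl, Cl_i_baseline = base$Cl_i,
    df_gabaa_baseline = base$df_gabaa,
    peak_response_mV = peak,
    polarity = ifelse(peak < 0, "hyperpolarizing", "depolarizing")
  )
}

experiment_times <- function(duration, pulse_times) {
  dense <- lapply(pulse_times, function(tt) seq(tt - 2, tt + 6, by = 0.02))
  sort(unique(c(seq(0, duration, by = 2), unlist(dense), duration)))
}

build_experiment <- function(params, ramp_events, pulse_times, duration,
                             state0 = NULL) {
  pulses <- lapply(pulse_times, function(tt) {
    gaba_pulse(tt, tau_ms = params$tau_ms, g_max_nS = params$g_GABAA_max)
  })
  protocol <- stim_protocol(c(pulses, ramp_events))
  if (is.null(state0)) state0 <- steady_state(params)
  simulate_model(params, protocol, duration = duration,
                 times = experiment_times(duration, pulse_times),
                 state0 = state0)
}

experiment_report <- function(sim, pulse_times, label) {
  traj <- sim$trajectory
  rep <- dplyr::bind_rows(lapply(pulse_times, measure_pulse, traj = traj))
  rep$phase <- c("baseline", "post")[seq_along(pulse_times)]
  rep$experiment <- label
  rep <- rep[, c("experiment", "phase", setdiff(names(rep),
                                                c("experiment", "phase")))]
  structure(list(report = rep, sim = sim), class = "df_experiment")
}

#' @export
print.df_experiment <- function(x, ...) {
  cat("<df_experiment>\n")
  print(x$report)
  invisible(x)
}

#' Simulated KCC2 block
#'
#' From the default steady state: a synaptic GABA-A pulse probes the baseline
#' response, `g_KCC2` is then ramped from its default to `g_block` across the
#' stated window (minutes 41-50 by default), the cell re-equilibrates, and a
#' second pulse probes the post-block response. Blocking chloride extrusion
#' raises intracellular chloride and `E_GABAA` far more than it moves `Vm`,
#' collapsing and inverting the driving force: the GABA response flips from
#' hyperpolarizing to depolarizing.
#'
#' @param params A [model_params()] object.
#' @param pulse_times Times of the two probe pulses (s); defaults 40 and
#'   70 min.
#' @param ramp_window Start/end of the conductance ramp (s); default minutes
#'   41-50.
#' @param g_block Post-ramp KCC2 conductance (uS/cm^2).
#' @param duration Total simulated time (s).
#' @param washback If `TRUE`, `g_KCC2` is ramped back to its default over one
#'   minute starting at `washback_at`, and the run is extended so recovery can
#'   be assessed.
#' @param washback_at Start of the restoring ramp (s).
#' @return A `df_experiment`: `report` (one row per probe pulse with baseline
#'   and post-manipulation `Vm`, `E_GABAA`, `Cl_i`, driving force, and the peak
#'   GABA-response amplitude and polarity) plus the full `ion_sim`.
#' @export
kcc2_block_experiment <- function(params = model_params(),
                                  pulse_times = c(40, 70) * 60,
                                  ramp_window = c(41, 50) * 60,
                                  g_block = 0,
                                  duration = 75 * 60,
                                  washback = FALSE,
                                  washback_at = 75 * 60) {
  ramp <- list(param_ramp("g_KCC2", params$g_KCC2, g_block,
                          ramp_window[1], ramp_window[2]))
  if (washback) {
    ramp <- c(ramp, list(param_ramp("g_KCC2", g_block, params$g_KCC2,
                                    washback_at, washback_at + 60)))
    duration <- max(duration, washback_at + 35 * 60)
  }
  sim <- build_experiment(params, ramp, pulse_times, duration)
  experiment_report(sim, pulse_times, "kcc2_block")
}

#' Simulated impermeant-anion charge shift
#'
#' As [kcc2_block_experiment()], but the manipulation is a linear ramp of the
#' average impermeant-anion charge `z_i` (default -0.85 to -1.05) at fixed
#' impermeant-anion amount. Adding negative impermeant charge drops `Vm` and
#' `E_GABAA` together (ionic redistribution keeps them proportional), lowers
#' intracellular chloride, and leaves the driving force - hence the GABA
#' response - almost unchanged.
#'
#' @inheritParams kcc2_block_experiment
#' @param z_target Post-ramp average impermeant charge.
#' @return A `df_experiment`.
#' @export
impermeant_anion_experiment <- function(params = model_params(),
                                        pulse_times = c(40, 70) * 60,
                                        ramp_window = c(41, 50) * 60,
                                        z_target = -1.05,
                                        duration = 75 * 60) {
  ramp <- list(param_ramp("z_i", params$z_i, z_target,
                          ramp_window[1], ramp_window[2]))
  sim <- build_experiment(params, ramp, pulse_times, duration)
  experiment_report(sim, pulse_times, "impermeant_anion_shift")
}
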