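# Ground-truth-labelled synthetic voltage-imaging data: step-like voltage
# deflections during optogenetic epochs, a linear fluorescence-voltage gain
# (fluorescence rises on hyperpolarization), slow photobleaching, background
# contamination and Poisson shot noise.

#' Synthetic imaging scenario
#'
#' Describes one synthetic recording: the true driving force, the stimulation
#' schedule, voltage kinetics, calibration, photon budget, bleaching,
#' background, and an optional seizure-like excursion. Defaults emulate the
#' published acquisition: five 2 s strobed activations every 5 s at 25 Hz,
#' ~36585 photoelectrons per frame, ~5% fluorescence loss per 25 s of
#' monoexponential bleaching, and a 50 ms voltage time constant (use
#' `tau_ms = 500` for an astrocyte-like slow response).
#'
#' @param true_df True driving force (mV, `Vm - E_GABAA` convention): each
#'   stimulation relaxes `Vm` from rest toward `rest - true_df`.
#' @param v_rest Resting potential (mV); only its changes matter optically.
#' @param n_epochs Number of stimulation epochs.
#' @param epoch_duration_s Stimulation duration (s).
#' @param epoch_period_s Time between epoch onsets (s).
#' @param first_onset_s Onset of the first epoch (s).
#' @param duration_s Recording length (s).
#' @param frame_rate Hz.
#' @param tau_ms Voltage relaxation time constant during and after
#'   stimulation (ms).
#' @param cal A [calibration()].
#' @param photons_per_frame Baseline signal photoelectrons per frame.
#' @param bleach_fraction_per_25s Monoexponential fluorescence loss over 25 s.
#' @param background_level Background photoelectrons per frame (shared
#'   contamination subtracted by the pipeline).
#' @param artefact Optional shared additive artefact:
#'   `list(amplitude, start, end)` (photoelectrons, s) added to both traces.
#' @param sle Optional seizure-like excursion
#'   `list(amplitude_mV, start, end)` superimposed on the voltage trace.
#' @param noise If `FALSE`, expected photon counts are returned without the
#'   Poisson draw.
#' @param mechanistic If `TRUE`, the voltage trace is produced by the
#'   pump-leak model ([simulate_model()]) with square anion-conductance pulses
#'   instead of the phenomenological kinetics.
#' @param params [model_params()] for mechanistic mode.
#' @param opto_g_nS Pulse conductance in mechanistic mode (nS).
#' @return A list of class `synth_scenario`.
#' @export
synth_scenario <- function(true_df = -6, v_rest = -67.2,
                           n_epochs = 5, epoch_duration_s = 2,
                           epoch_period_s = 5, first_onset_s = 2.5,
                           duration_s = 25, frame_rate = 25,
                           tau_ms = 50,
                           cal = calibration(),
                           photons_per_frame = 36585.37,
                           bleach_fraction_per_25s = 0.05,
                           background_level = 3000,
                           artefact = NULL, sle = NULL,
                           noise = TRUE,
                           mechanistic = FALSE,
                           params = NULL, opto_g_nS = 10) {
  stopifnot(photons_per_frame > 0, frame_rate > 0, n_epochs >= 1,
            epoch_duration_s > 0, tau_ms > 0, background_level >= 0,
            bleach_fraction_per_25s >= 0, bleach_fraction_per_25s < 1)
  onsets <- first_onset_s + epoch_period_s * (seq_len(n_epochs) - 1)
  if (max(onsets) + epoch_duration_s > duration_s) {
    stop("stimulation schedule does not fit in the recording", call. = FALSE)
  }
  if (onsets[1] < epoch_duration_s) {
    stop("first epoch leaves no room for an equal-length baseline",
         call. = FALSE)
  }
  structure(list(
    true_df = true_df, v_rest = v_rest,
    onsets = onsets, epoch_duration_s = epoch_duration_s,
    duration_s = duration_s, frame_rate = frame_rate, tau_ms = tau_ms,
    cal = cal, photons_per_frame = photons_per_frame,
    bleach_rate = if (bleach_fraction_per_25s > 0) {
      -log(1 - bleach_fraction_per_25s) / 25
    } else 0,
    background_level = background_level, artefact = artefact, sle = sle,
    noise = noise, mechanistic = mechanistic, params = params,
    opto_g_nS = opto_g_nS
  ), class = "synth_scenario")
}

frame_times <- function(scenario) {
  n <- floor(scenario$duration_s * scenario$frame_rate)
  (seq_len(n) - 1) / scenario$frame_rate
}

#' Synthetic membrane-potential trace
#'
#' During each stimulation epoch, `Vm` relaxes exponentially from rest toward
#' `rest - true_df` with the scenario's time constant, and relaxes back after
#' the epoch ends; an optional seizure-like excursion is superimposed. In
#' mechanistic mode, the trace is the pump-leak model's `Vm` under square
#' anion-conductance pulses, so the stimulated plateau sits at the model's own
#' GABA-A reversal potential.
#'
#' @param scenario A [synth_scenario()].
#' @param times Sample times (s); defaults to the scenario's frame times.
#' @return Voltage samples (mV).
#' @export
generate_vm_trace <- function(scenario, times = frame_times(scenario)) {
  if (isTRUE(scenario$mechanistic)) {
    params <- scenario$params %||% model_params()
    pulses <- lapply(scenario$onsets, function(on) {
      opto_pulse(on, on + scenario$epoch_duration_s, g_nS = scenario$opto_g_nS)
    })
    sim <- simulate_model(params, stim_protocol(pulses),
                          duration = scenario$duration_s,
                          times = sort(unique(c(times, 0,
                                                scenario$duration_s))),
                          state0 = steady_state(params))
    return(stats::approx(sim$trajectory$t, sim$trajectory$Vm,
                         xout = times)$y)
  }
  tau <- scenario$tau_ms * 1e-3
  v <- rep(scenario$v_rest, length(times))
  target <- -scenario$true_df
  for (on in scenario$onsets) {
    off <- on + scenario$epoch_duration_s
    during <- times >= on & times < off
    after <- times >= off
    v[during] <- v[during] + target * (1 - exp(-(times[during] - on) / tau))
    d_off <- target * (1 - exp(-(off - on) / tau))
    v[after] <- v[after] + d_off * exp(-(times[after] - off) / tau)
  }
  if (!is.null(scenario$sle)) {
    s <- scenario$sle
    v[times >= s$start & times < s$end] <- v[times >= s$start & times < s$end] +
      s$amplitude_mV
  }
  v
}

#' Expected photon counts from a voltage trace
#'
#' Linear indicator model with bleaching:
#' `F(t) = F0 * bleach(t) * (1 + slope/100 * (V_rest - Vm(t)))`, so
#' fluorescence increases when the membrane hyperpolarizes.
#'
#' @param vm_trace Voltage samples (mV).
#' @param scenario A [synth_scenario()].
#' @param times Sample times (s).
#' @return Expected signal photoelectrons per frame (strictly positive).
#' @export
vm_to_fluorescence <- function(vm_trace, scenario,
                               times = frame_times(scenario)) {
  s <- scenario$cal$slope_percent_per_mV
  if (s == 0) stop("calibration slope must be non-zero", call. = FALSE)
  gain <- 1 + s / 100 * (scenario$v_rest - vm_trace)
  f <- scenario$photons_per_frame * exp(-scenario$bleach_rate * times) * gain
  if (any(f <= 0)) {
    stop("scenario drives expected fluorescence non-positive", call. = FALSE)
  }
  f
}

#' Poisson shot noise
#'
#' Independent Poisson draw per frame around the expected photon counts;
#' reproducible for a given seed.
#'
#' @param expected_counts Expected photoelectrons per frame (>= 0).
#' @param seed Optional integer seed.
#' @return Observed counts.
#' @export
add_shot_noise <- function(expected_counts, seed = NULL) {
  if (any(expected_counts < 0)) {
    stop("expected counts must be >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  stats::rpois(length(expected_counts), expected_counts)
}

#' Render a synthetic recording with its ground-truth manifest
#'
#' Composes [generate_vm_trace()], [vm_to_fluorescence()] and
#' [add_shot_noise()] into ROI and background traces. The background trace is
#' the configured level (bleached) plus any shared artefact plus its own shot
#' noise; the ROI trace additionally contains the voltage-dependent signal.
#' The manifest records every generative parameter, the per-epoch true dF/F0
#' and voltage shift, and the seed; analysis needs nothing beyond the
#' recording and the calibration.
#'
#' @param scenario A [synth_scenario()].
#' @param seed Integer seed for the shot noise.
#' @return A list with `recording` ([fluor_recording()]) and `manifest`.
#' @export
#' @examples
#' r <- render_recording(synth_scenario(true_df = -6), seed = 1)
#' estimate_df_gabaa(r$recording)
render_recording <- function(scenario, seed = 1) {
  times <- frame_times(scenario)
  vm <- generate_vm_trace(scenario, times)
  f_sig <- vm_to_fluorescence(vm, scenario, times)
  bleach <- exp(-scenario$bleach_rate * times)
  art <- rep(0, length(times))
  if (!is.null(scenario$artefact)) {
    a <- scenario$artefact
    art[times >= a$start & times < a$end] <- a$amplitude
  }
  bg_expected <- scenario$background_level * bleach + art
  roi_expected <- f_sig + bg_expected
  if (isTRUE(scenario$noise)) {
    set.seed(seed)
    roi <- stats::rpois(length(times), roi_expected)
    bg <- stats::rpois(length(times), bg_expected)
  } else {
    roi <- roi_expected
    bg <- bg_expected
  }
  windows <- tibble::tibble(start = scenario$onsets,
                            end = scenario$onsets + scenario$epoch_duration_s,
                            kind = "optogenetic")
  per_epoch <- purrr::map_dfr(seq_along(scenario$onsets), function(k) {
    idx <- times >= windows$start[k] & times < windows$end[k]
    dv <- mean(vm[idx]) - scenario$v_rest
    tibble::tibble(epoch = k, true_delta_v = dv,
                   true_dff = scenario$cal$slope_percent_per_mV / 100 * (-dv))
  })
  rec <- fluor_recording(times, roi, bg, windows,
                         frame_rate = scenario$frame_rate,
                         metadata = list(seed = seed, synthetic = TRUE))
  manifest <- list(
    scenario = scenario[setdiff(names(scenario), c("cal", "params"))],
    calibration = unclass(scenario$cal),
    per_epoch = per_epoch,
    seed = seed
  )
  list(recording = rec, manifest = manifest)
}
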