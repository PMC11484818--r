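# Photon-budget design: shot-noise-limited SNR for voltage imaging, assuming
# negligible dark and read noise so the per-frame noise is sqrt(F0).

#' Acquisition specification
#'
#' Camera and protocol parameters that determine the shot-noise-limited SNR of
#' a fluorescence measurement.
#'
#' @param well_depth Sensor well depth (electrons).
#' @param quantum_efficiency Peak quantum efficiency (fraction in (0, 1]).
#' @param frame_rate Acquisition rate (Hz).
#' @param stimulus_duration Optogenetic stimulation time per epoch (s).
#' @param target_dff Signal to detect (dF/F0, fraction).
#' @param target_snr Desired signal-to-noise ratio.
#' @return A list of class `acquisition_spec`.
#' @export
acquisition_spec <- function(well_depth = 30000, quantum_efficiency = 0.82,
                             frame_rate = 25, stimulus_duration = 1,
                             target_dff = 0.01, target_snr = 10) {
  stopifnot(well_depth > 0, quantum_efficiency > 0, quantum_efficiency <= 1,
            frame_rate > 0, stimulus_duration > 0, target_dff > 0,
            target_snr >= 0)
  structure(list(well_depth = well_depth,
                 quantum_efficiency = quantum_efficiency,
                 frame_rate = frame_rate,
                 stimulus_duration = stimulus_duration,
                 target_dff = target_dff, target_snr = target_snr),
            class = "acquisition_spec")
}

#' Electrons collected per frame
#'
#' `well_depth / quantum_efficiency`: the photoelectron budget implied by
#' filling the sensor well at the stated quantum efficiency (36585.37 for the
#' default 30000 e- well at 82%).
#'
#' @param spec An [acquisition_spec()].
#' @return Electrons per frame.
#' @export
electrons_per_frame <- function(spec = acquisition_spec()) {
  spec$well_depth / spec$quantum_efficiency
}

#' Baseline photons required for a target SNR
#'
#' From `SNR = dF / sqrt(F0)` with `dF = dFF * F0`:
#' `F0 = (SNR / dFF)^2` (1e6 photons for SNR 10 at 1% dF/F0).
#'
#' @param target_snr Desired SNR.
#' @param target_dff Signal (dF/F0 fraction), > 0.
#' @return Required baseline photon count `F0`.
#' @export
required_f0 <- function(target_snr, target_dff) {
  stopifnot(target_dff > 0)
  (target_snr / target_dff)^2
}

#' Frames required to accumulate a photon budget
#'
#' @param f0 Required baseline photon count.
#' @param epf Electrons per frame.
#' @return A list with `frames` (unrounded) and `frames_ceiling`.
#' @export
frames_required <- function(f0, epf) {
  stopifnot(epf > 0)
  list(frames = f0 / epf, frames_ceiling = ceiling(f0 / epf))
}

#' Expected SNR of one stimulation epoch
#'
#' Shot-noise-limited SNR of a dF/F0 measurement accumulated over one
#' stimulation: `SNR = dFF * sqrt(epf * frame_rate * stimulus_duration)`
#' (single-frame SNR scaled by the square root of the number of frames).
#' With the default camera this gives ~9.6 for a 1 s stimulation at 25 Hz and
#' ~13.5 for 2 s.
#'
#' @param spec An [acquisition_spec()].
#' @return Dimensionless SNR.
#' @export
snr_for_stimulation <- function(spec = acquisition_spec()) {
  n_frames <- spec$frame_rate * spec$stimulus_duration
  spec$target_dff * sqrt(electrons_per_frame(spec) * n_frames)
}

#' Predicted shot-noise SD of a driving-force estimate
#'
#' A-priori standard deviation of the pipeline's driving-force estimate under
#' the same Poisson model as the SNR chain, extended with the two terms the
#' estimator actually incurs: the stimulus-period mean and the baseline-period
#' mean each carry shot noise (variance `(F0 + B)/N` per mean, with `B` the
#' background photons included in the ROI), giving
#' `SD(dFF) = sqrt((F0 + B) * (1/N_stim + 1/N_base)) / F0`, converted to mV
#' through the calibration.
#'
#' @param epf Signal photoelectrons per frame (F0).
#' @param n_stim_frames,n_base_frames Frames averaged in the stimulus and
#'   baseline periods (across all epochs).
#' @param background Background photoelectrons per frame contaminating the
#'   ROI.
#' @param cal A [calibration()].
#' @return A list with `sd_dff` (fraction) and `sd_mV`.
#' @export
predicted_df_sd <- function(epf, n_stim_frames, n_base_frames = n_stim_frames,
                            background = 0, cal = calibration()) {
  stopifnot(epf > 0, n_stim_frames >= 1, n_base_frames >= 1, background >= 0)
  sd_dff <- sqrt((epf + background) *
                   (1 / n_stim_frames + 1 / n_base_frames)) / epf
  list(sd_dff = sd_dff,
       sd_mV = sd_dff * 100 / cal$slope_percent_per_mV)
}

#' Predicted estimator SD through the full analysis pipeline
#'
#' Every stage of the epoch-average pipeline (background smoothing and
#' subtraction, polynomial detrending with response exclusion, epoch averaging
#' and the window means) is linear in the photon counts, so the shot-noise
#' standard deviation of the driving-force estimate can be propagated exactly:
#' `var(dFF) = sum(a_roi^2 * lambda_roi) + sum(a_bg^2 * lambda_bg)` scaled by
#' `F0^-2`, where the weight vectors are the window-mean contrast pulled back
#' through the detrend prediction operator and the background-smoothing
#' matrix, and `lambda` are the expected (noiseless) counts. This captures the
#' variance amplification caused by the high-order polynomial interpolating
#' across the excluded stimulation windows, which the single-epoch SNR chain
#' ([snr_for_stimulation()], [predicted_df_sd()]) deliberately ignores.
#'
#' @param rec A noiseless [fluor_recording()] template carrying the expected
#'   photon counts (e.g. `render_recording(scenario_without_noise)`).
#' @param detrend_order,bg_smooth_window,exclude_pad_s,n_epochs Pipeline
#'   settings, as in [estimate_df_gabaa()].
#' @param cal A [calibration()].
#' @return A list with `sd_dff` and `sd_mV`.
#' @export
pipeline_df_sd <- function(rec, detrend_order = 9, bg_smooth_window = 100,
                           exclude_pad_s = 0.5, n_epochs = NULL,
                           cal = calibration()) {
  stopifnot(inherits(rec, "fluor_recording"))
  tm <- rec$data$time
  n <- length(tm)
  lam_roi <- rec$data$roi
  lam_bg <- rec$data$background
  sw <- rec$stimulus_windows
  if (is.null(n_epochs)) n_epochs <- nrow(sw)
  excl <- windows_to_mask(n, purrr::pmap(sw[c("start", "end")],
                                         function(start, end) {
                                           c(start, end + exclude_pad_s)
                                         }), tm)
  wf <- window_frames(rec)[seq_len(n_epochs)]
  len <- wf[[1]][2] - wf[[1]][1] + 1
  stim_idx <- unlist(lapply(wf, function(w) seq(w[1], w[2])))
  base_idx <- unlist(lapply(wf, function(w) seq(w[1] - len, w[1] - 1)))
  m <- numeric(n)
  m[stim_idx] <- 1 / length(stim_idx)
  m[base_idx] <- m[base_idx] - 1 / length(base_idx)
  # pull the contrast back through the detrend prediction operator
  xs <- (tm - mean(tm[!excl])) / stats::sd(tm[!excl])
  B <- if (detrend_order == 0) {
    matrix(1, n, 1)
  } else {
    cbind(1, stats::poly(xs, detrend_order, raw = FALSE))
  }
  Binc <- B[!excl, , drop = FALSE]
  mt <- m
  mt[!excl] <- mt[!excl] -
    as.numeric(Binc %*% solve(crossprod(Binc), crossprod(B, m)))
  # ... and through the background-smoothing matrix
  left <- (as.integer(bg_smooth_window) - 1L) %/% 2L
  right <- as.integer(bg_smooth_window) %/% 2L
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  smt <- numeric(n)
  for (i in seq_len(n)) {
    smt[lo[i]:hi[i]] <- smt[lo[i]:hi[i]] + mt[i] / (hi[i] - lo[i] + 1L)
  }
  corrected <- subtract_background(lam_roi, lam_bg, bg_smooth_window)
  f0 <- mean(corrected[base_idx])
  sd_dff <- sqrt(sum(mt^2 * lam_roi) + sum(smt^2 * lam_bg)) / abs(f0)
  list(sd_dff = sd_dff, sd_mV = sd_dff * 100 / abs(cal$slope_percent_per_mV))
}

#' Acquisition design report
#'
#' Chains the photon-budget calculation for an acquisition specification:
#' electrons per frame, required `F0`, frames needed, and the expected SNR of
#' one stimulation epoch.
#'
#' @param spec An [acquisition_spec()].
#' @return A one-row tibble.
#' @export
#' @examples
#' design_report(acquisition_spec())
design_report <- function(spec = acquisition_spec()) {
  epf <- electrons_per_frame(spec)
  f0 <- required_f0(spec$target_snr, spec$target_dff)
  fr <- frames_required(f0, epf)
  tibble::tibble(
    well_depth = spec$well_depth,
    quantum_efficiency = spec$quantum_efficiency,
    electrons_per_frame = epf,
    target_dff = spec$target_dff,
    target_snr = spec$target_snr,
    required_f0 = f0,
    frames_required = fr$frames,
    frames_required_ceiling = fr$frames_ceiling,
    frame_rate = spec$frame_rate,
    stimulus_duration = spec$stimulus_duration,
    expected_snr = snr_for_stimulation(spec)
  )
}
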