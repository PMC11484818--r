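#' Fluorescence recording container
#'
#' Bundles equal-length ROI and background fluorescence traces with their
#' frame times, the stimulus windows, and acquisition metadata. Stimulus
#' windows are half-open intervals `[start, end)` in seconds.
#'
#' @param time Frame times (s), strictly increasing.
#' @param roi ROI trace (integrated density, i.e. mean pixel brightness).
#' @param background Background-ROI trace, same length.
#' @param stimulus_windows Tibble/data frame with `start`, `end` (s) and
#'   optionally `kind` (`"optogenetic"` or `"agonist_puff"`).
#' @param frame_rate Acquisition rate (Hz); inferred from `time` when `NULL`.
#' @param metadata Optional named list (exposure, dye, etc.).
#' @return A list of class `fluor_recording` with elements `data` (tibble:
#'   `time`, `roi`, `background`), `stimulus_windows`, `frame_rate`,
#'   `metadata`.
#' @export
fluor_recording <- function(time, roi, background,
                            stimulus_windows = NULL, frame_rate = NULL,
                            metadata = list()) {
  if (length(time) != length(roi) || length(roi) != length(background)) {
    stop("time, roi and background must have equal length", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  inferred <- if (length(time) >= 2) 1 / stats::median(diff(time)) else NA
  if (is.null(frame_rate)) {
    if (!is.finite(inferred)) {
      stop("frame rate must be declared for single-frame recordings",
           call. = FALSE)
    }
    frame_rate <- inferred
  } else if (is.finite(inferred) &&
             abs(frame_rate - inferred) / frame_rate > 0.01) {
    stop(sprintf(
      "declared frame rate (%.4g Hz) disagrees with the time column (%.4g Hz)",
      frame_rate, inferred), call. = FALSE)
  }
  if (frame_rate <= 0) stop("frame rate must be > 0", call. = FALSE)
  if (is.null(stimulus_windows)) {
    stimulus_windows <- tibble::tibble(start = numeric(), end = numeric(),
                                       kind = character())
  }
  stimulus_windows <- tibble::as_tibble(stimulus_windows)
  if (!"kind" %in% names(stimulus_windows)) {
    stimulus_windows$kind <- rep("optogenetic", nrow(stimulus_windows))
  }
  if (nrow(stimulus_windows) > 0 &&
      (min(stimulus_windows$start) < min(time) ||
       max(stimulus_windows$end) > max(time) + 1 / frame_rate)) {
    stop("stimulus windows must lie within the recording span", call. = FALSE)
  }
  structure(list(
    data = tibble::tibble(time = time, roi = roi, background = background),
    stimulus_windows = stimulus_windows,
    frame_rate = frame_rate,
    metadata = metadata
  ), class = "fluor_recording")
}

#' @export
print.fluor_recording <- function(x, ...) {
  cat(sprintf("<fluor_recording> %d frames @ %.4g Hz, %d stimulus window(s)\n",
              nrow(x$data), x$frame_rate, nrow(x$stimulus_windows)))
  invisible(x)
}

frames_in_window <- function(time, start, end) {
  which(time >= start & time < end)
}

# stimulus windows (s) -> frame-index windows c(first, last)
window_frames <- function(rec, windows = rec$stimulus_windows) {
  purrr::pmap(windows[c("start", "end")], function(start, end) {
    idx <- frames_in_window(rec$data$time, start, end)
    if (length(idx) == 0) stop("empty stimulus window", call. = FALSE)
    c(idx[1], idx[length(idx)])
  })
}

#' Estimate the GABA-A driving force from a fluorescence recording
#'
#' Composes the full analysis pipeline and converts the resulting dF/F0 into a
#' driving-force estimate in mV. Three modes mirror the three published
#' recording configurations:
#'
#' * `"epoch_average"` (in-vitro all-optical): background subtracted after
#'   smoothing with `bg_smooth_window` frames, polynomial detrend with the
#'   stimulation epochs excluded, the stimulation epochs and their preceding
#'   equal-length baselines averaged, and a mean-mode dF/F0 taken.
#' * `"extremum"` (agonist puff): raw background subtraction, detrend, centred
#'   smoothing (`smooth_window` frames), dF/F0 from the post-stimulus extremum
#'   against the pre-stimulus baseline mean.
#' * `"in_vivo"`: single-stimulus dF/F0 with neuropil correction from the
#'   background trace ([in_vivo_dff()]).
#'
#' Detrending removes the absolute fluorescence level, so the dF/F0
#' denominator `F0` is taken from the background-corrected (not detrended)
#' trace over the baseline frames.
#'
#' The returned driving force follows the convention `DF = Vm - E_GABAA`:
#' activation drags `Vm` toward `E_GABAA`, so the measured voltage shift is
#' `delta_v = -DF` and a hyperpolarizing response (fluorescence increase,
#' positive dF/F0) yields a positive driving force. Use [df_as_shift()] for
#' the measured-shift presentation.
#'
#' @param rec A [fluor_recording()].
#' @param cal A [calibration()].
#' @param mode Pipeline variant (see above).
#' @param detrend_order Polynomial order for the bleach correction.
#' @param bg_smooth_window Background smoothing window (frames) for
#'   `epoch_average`; the puff pipeline always subtracts raw background.
#' @param smooth_window Display/extremum smoothing window (frames).
#' @param n_epochs Number of epochs averaged in `epoch_average` mode
#'   (default: all stimulus windows).
#' @param exclude_pad_s Padding (s) appended after each stimulus window when
#'   excluding the response from the polynomial fit.
#' @param response_s Response-window length (s) after stimulus onset for
#'   `extremum` mode.
#' @param flank_side `"before"` or `"after"`: side of the stimulus used for
#'   the in-vivo baseline flank.
#' @return A list of class `df_estimate` with `dff` (fraction), `delta_v`
#'   (mV, measured shift), `df_gabaa` (mV, `Vm - E_GABAA` convention), `mode`,
#'   and the windows used.
#' @export
estimate_df_gabaa <- function(rec, cal = calibration(),
                              mode = c("epoch_average", "extremum", "in_vivo"),
                              detrend_order = 9,
                              bg_smooth_window = 100,
                              smooth_window = 7,
                              n_epochs = NULL,
                              exclude_pad_s = 0.5,
                              response_s = 2,
                              flank_side = "before") {
  mode <- match.arg(mode)
  stopifnot(inherits(rec, "fluor_recording"))
  tm <- rec$data$time
  sw <- rec$stimulus_windows
  if (nrow(sw) == 0) stop("recording has no stimulus windows", call. = FALSE)
  excl <- purrr::pmap(sw[c("start", "end")], function(start, end) {
    c(start, end + exclude_pad_s)
  })

  if (mode == "epoch_average") {
    if (is.null(n_epochs)) n_epochs <- nrow(sw)
    corrected <- subtract_background(rec$data$roi, rec$data$background,
                                     bg_smooth_window)
    detrended <- detrend_polynomial(corrected, detrend_order, excl, times = tm)
    wf <- window_frames(rec)
    len <- wf[[1]][2] - wf[[1]][1] + 1
    base_idx <- unlist(lapply(wf[seq_len(n_epochs)], function(w) {
      seq(w[1] - len, w[1] - 1)
    }))
    f0 <- mean(corrected[base_idx])
    if (f0 == 0) stop("zero baseline fluorescence", call. = FALSE)
    avg <- average_epochs(detrended, wf, n_epochs)
    dff <- (mean(avg$stimulus) - mean(avg$baseline)) / f0
    used <- list(stimulus = sw[seq_len(n_epochs), ], baseline_frames = base_idx)
  } else if (mode == "extremum") {
    corrected <- subtract_background(rec$data$roi, rec$data$background, 1)
    detrended <- detrend_polynomial(corrected, detrend_order, excl, times = tm)
    smoothed <- moving_average(detrended, smooth_window)
    onset <- sw$start[1]
    resp_idx <- frames_in_window(tm, onset, onset + response_s)
    base_idx <- frames_in_window(tm, max(tm[1], onset - response_s), onset)
    if (length(base_idx) < 2 || length(resp_idx) < 1) {
      stop("not enough baseline or response samples around the stimulus",
           call. = FALSE)
    }
    f0 <- mean(moving_average(corrected, smooth_window)[base_idx])
    if (f0 == 0) stop("zero baseline fluorescence", call. = FALSE)
    dev <- smoothed[resp_idx] - mean(smoothed[base_idx])
    dff <- unname(dev[which.max(abs(dev))] / f0)
    used <- list(stimulus = sw[1, ], baseline_frames = base_idx,
                 response_frames = resp_idx)
  } else {
    onset <- sw$start[1]
    stim_idx <- frames_in_window(tm, onset, sw$end[1])
    dur <- sw$end[1] - onset
    flank <- if (identical(flank_side, "before")) {
      c(onset - dur, onset)
    } else {
      c(sw$end[1], sw$end[1] + dur)
    }
    flank_idx <- frames_in_window(tm, flank[1], flank[2])
    m <- min(length(stim_idx), length(flank_idx))
    stim_idx <- stim_idx[seq_len(m)]
    flank_idx <- flank_idx[seq_len(m)]
    dff <- in_vivo_dff(rec$data$roi, rec$data$background,
                       c(stim_idx[1], stim_idx[m]),
                       c(flank_idx[1], flank_idx[m]))
    used <- list(stimulus = sw[1, ], flank_frames = flank_idx)
  }

  delta_v <- dff_to_voltage(dff, cal)
  structure(list(dff = dff, delta_v = delta_v, df_gabaa = -delta_v,
                 mode = mode, windows = used, calibration = cal),
            class = "df_estimate")
}

#' @export
print.df_estimate <- function(x, ...) {
  cat(sprintf(
    "<df_estimate> mode=%s  dF/F0 = %.4f%%  delta_V = %.3f mV  DF = %.3f mV\n",
    x$mode, 100 * x$dff, x$delta_v, x$df_gabaa))
  invisible(x)
}

#' Measured-shift presentation of a driving-force estimate
#'
#' Returns the estimate as the optically measured membrane-potential shift
#' (`-DF`), the sign convention in which hyperpolarizing responses are
#' negative.
#'
#' @param x A `df_estimate`.
#' @return The shift in mV.
#' @export
df_as_shift <- function(x) {
  stopifnot(inherits(x, "df_estimate"))
  x$delta_v
}
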