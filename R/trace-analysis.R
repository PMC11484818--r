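# ROI-trace processing: background subtraction, photobleach detrending,
# smoothing, dF/F0 extraction and conversion to a driving-force estimate.

#' Centred moving average
#'
#' Moving average with a centred window that shrinks at the trace edges (the
#' first and last samples average over however much of the window fits).
#' `window = 1` is the identity. Even windows take one extra sample on the
#' right of the centre.
#'
#' @param trace Numeric vector.
#' @param window Window length in frames (>= 1).
#' @return Smoothed vector of the same length.
#' @export
moving_average <- function(trace, window) {
  stopifnot(window >= 1)
  window <- as.integer(window)
  if (window == 1L) return(trace)
  n <- length(trace)
  left <- (window - 1L) %/% 2L
  right <- window %/% 2L
  cs <- cumsum(c(0, trace))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Background subtraction
#'
#' Subtracts a (smoothed) background-ROI trace from the cell-ROI trace. The
#' background is smoothed with a centred moving average of `smooth_window`
#' frames before subtraction; `smooth_window = 1` subtracts it raw (the
#' agonist-puff pipeline), while the all-optical pipeline uses a long window
#' (default 100 frames) so only the slow background component is removed.
#'
#' @param roi_trace,background_trace Equal-length numeric vectors.
#' @param smooth_window Background smoothing window (frames).
#' @return Background-corrected trace.
#' @export
subtract_background <- function(roi_trace, background_trace,
                                smooth_window = 100) {
  if (length(roi_trace) != length(background_trace)) {
    stop("roi and background traces must have equal length", call. = FALSE)
  }
  roi_trace - moving_average(background_trace, smooth_window)
}

windows_to_mask <- function(n, windows, times = NULL) {
  mask <- rep(FALSE, n)
  if (is.null(windows)) return(mask)
  if (is.data.frame(windows)) {
    windows <- purrr::pmap(windows[c("start", "end")], function(start, end) {
      c(start, end)
    })
  }
  if (is.numeric(windows) && !is.list(windows)) windows <- list(windows)
  for (wn in windows) {
    if (is.null(times)) {
      idx <- seq(max(1, ceiling(wn[1])), min(n, floor(wn[2])))
      mask[idx] <- TRUE
    } else {
      mask[times >= wn[1] & times < wn[2]] <- TRUE
    }
  }
  mask
}

#' Polynomial detrending with response exclusion
#'
#' Fits a polynomial of the given order by least squares to the samples
#' outside `exclude_windows` (so the response itself does not bias the fit),
#' evaluates it over the whole trace and subtracts it. This removes
#' photobleaching and other slow drifts; the non-excluded residuals have mean
#' ~0, so callers needing an absolute fluorescence level must retain it
#' separately (see [estimate_df_gabaa()]).
#'
#' @param trace Numeric vector.
#' @param order Polynomial order (>= 0); the published pipeline uses 9 or 10.
#' @param exclude_windows Frame-index windows `list(c(start, end), ...)` (or a
#'   two-column data frame `start`/`end`) excluded from the fit. `NULL`
#'   excludes nothing.
#' @param times Optional sample times; when given, windows are interpreted in
#'   those units (half-open `[start, end)`).
#' @return Detrended trace.
#' @export
detrend_polynomial <- function(trace, order = 9, exclude_windows = NULL,
                               times = NULL) {
  stopifnot(order >= 0)
  n <- length(trace)
  x <- if (is.null(times)) seq_len(n) else times
  excl <- windows_to_mask(n, exclude_windows, times)
  keep <- which(!excl)
  if (length(keep) < order + 2) {
    stop("underdetermined fit: need at least ", order + 2,
         " samples outside the excluded windows, have ", length(keep),
         call. = FALSE)
  }
  xs <- (x - mean(x[keep])) / stats::sd(x[keep])
  if (order == 0) {
    trend <- rep(mean(trace[keep]), n)
  } else {
    fit <- stats::lm(y ~ stats::poly(xs, order, raw = FALSE),
                     data = data.frame(y = trace[keep], xs = xs[keep]))
    trend <- as.numeric(stats::predict(fit, newdata = data.frame(xs = xs)))
  }
  trace - trend
}

#' Event dF/F0
#'
#' Fractional fluorescence change of a response window against a baseline
#' window. In `extremum` mode the response value is the sample deviating most
#' from the baseline mean (the maximum or minimum of the smoothed signal,
#' whichever deviates further); in `mean` mode it is the response-window mean.
#'
#' @param trace Numeric vector.
#' @param baseline_window,response_window Frame-index windows `c(start, end)`
#'   (inclusive indices), disjoint and inside the trace.
#' @param mode `"extremum"` or `"mean"`.
#' @return dF/F0 as a fraction.
#' @export
dff_event <- function(trace, baseline_window, response_window,
                      mode = c("extremum", "mean")) {
  mode <- match.arg(mode)
  n <- length(trace)
  bi <- seq(baseline_window[1], baseline_window[2])
  ri <- seq(response_window[1], response_window[2])
  if (min(bi, ri) < 1 || max(bi, ri) > n) {
    stop("windows must lie inside the trace", call. = FALSE)
  }
  if (length(intersect(bi, ri)) > 0) {
    stop("baseline and response windows must be disjoint", call. = FALSE)
  }
  f0 <- mean(trace[bi])
  if (f0 == 0) stop("zero baseline mean; dF/F0 undefined", call. = FALSE)
  if (mode == "mean") {
    return((mean(trace[ri]) - f0) / f0)
  }
  dev <- trace[ri] - f0
  unname(dev[which.max(abs(dev))] / f0)
}

#' Average stimulation epochs
#'
#' Sample-wise average of `n_epochs` equal-length stimulus segments and of the
#' equal-length baseline segments immediately preceding each (the strobed
#' multi-activation protocol averages its repeats before dF/F0 is computed).
#'
#' @param trace Numeric vector.
#' @param stimulus_windows List (or `start`/`end` data frame) of frame-index
#'   windows, all of one length, each preceded by room for a baseline of the
#'   same length.
#' @param n_epochs Number of epochs to average (defaults to all).
#' @return A list with `stimulus` and `baseline` averaged segments.
#' @export
average_epochs <- function(trace, stimulus_windows,
                           n_epochs = length(stimulus_windows)) {
  if (is.data.frame(stimulus_windows)) {
    stimulus_windows <- purrr::pmap(stimulus_windows[c("start", "end")],
                                    function(start, end) c(start, end))
  }
  stopifnot(n_epochs >= 1, length(stimulus_windows) >= n_epochs)
  stimulus_windows <- stimulus_windows[seq_len(n_epochs)]
  lens <- vapply(stimulus_windows, function(w) w[2] - w[1] + 1, numeric(1))
  if (length(unique(lens)) != 1) {
    stop("stimulus epochs must all have the same length", call. = FALSE)
  }
  len <- lens[1]
  stim <- matrix(NA_real_, nrow = len, ncol = n_epochs)
  base <- matrix(NA_real_, nrow = len, ncol = n_epochs)
  for (k in seq_len(n_epochs)) {
    w <- stimulus_windows[[k]]
    if (w[1] - len < 1 || w[2] > length(trace)) {
      stop("epoch ", k, " (or its baseline) lies outside the trace",
           call. = FALSE)
    }
    stim[, k] <- trace[seq(w[1], w[2])]
    base[, k] <- trace[seq(w[1] - len, w[1] - 1)]
  }
  list(stimulus = rowMeans(stim), baseline = rowMeans(base))
}

#' In-vivo dF/F0 with neuropil correction
#'
#' For recordings with high spontaneous activity, dF is taken from a single
#' stimulus window against an equal-duration flank, and an equivalent dF
#' computed on the background trace over the same index windows is subtracted
#' to remove shared (neuropil) contamination:
#' `dFF = (dF_S - dF_BG) / F0_S` with `F0_S` the ROI flank mean.
#'
#' @param roi_trace,background_trace Equal-length numeric vectors.
#' @param stim_window,flank_window Equal-length frame-index windows
#'   `c(start, end)`.
#' @return dF/F0 as a fraction.
#' @export
in_vivo_dff <- function(roi_trace, background_trace, stim_window,
                        flank_window) {
  if (length(roi_trace) != length(background_trace)) {
    stop("roi and background traces must have equal length", call. = FALSE)
  }
  si <- seq(stim_window[1], stim_window[2])
  fi <- seq(flank_window[1], flank_window[2])
  if (length(si) != length(fi)) {
    stop("stimulus and flank windows must have equal duration", call. = FALSE)
  }
  f0s <- mean(roi_trace[fi])
  if (f0s == 0) stop("zero F0; dF/F0 undefined", call. = FALSE)
  df_s <- mean(roi_trace[si]) - f0s
  df_bg <- mean(background_trace[si]) - mean(background_trace[fi])
  (df_s - df_bg) / f0s
}

#' Fluorescence-to-voltage calibration
#'
#' Linear calibration of a voltage indicator: `slope_percent_per_mV` percent
#' dF/F0 per millivolt of membrane-potential change, with a flag recording the
#' indicator's sign convention (the bundled default, from the JF608-labelled
#' indicator, is 0.1845 %/mV with fluorescence increasing on
#' hyperpolarization, i.e. ~5.42 mV per dF/F0 percent).
#'
#' @param slope_percent_per_mV Calibration slope (%/mV), non-zero.
#' @param fluor_increases_on_hyperpol Sign convention flag.
#' @return A list of class `df_calibration`.
#' @export
calibration <- function(slope_percent_per_mV = 0.1845,
                        fluor_increases_on_hyperpol = TRUE) {
  if (slope_percent_per_mV == 0) stop("calibration slope must be non-zero",
                                      call. = FALSE)
  structure(list(slope_percent_per_mV = slope_percent_per_mV,
                 fluor_increases_on_hyperpol = fluor_increases_on_hyperpol),
            class = "df_calibration")
}

#' Convert dF/F0 to a membrane-potential change
#'
#' `delta_V = -(dFF * 100) / slope` under the default convention that
#' fluorescence rises when the membrane hyperpolarizes; with the bundled slope
#' a +1% dF/F0 maps to a -5.42 mV shift.
#'
#' @param dff dF/F0 (fraction).
#' @param cal A [calibration()].
#' @return Voltage change in mV.
#' @export
dff_to_voltage <- function(dff, cal = calibration()) {
  sgn <- if (cal$fluor_increases_on_hyperpol) -1 else 1
  sgn * dff * 100 / cal$slope_percent_per_mV
}
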