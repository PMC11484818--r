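# Event detection on voltage traces: seizure-like events and network bursts.

baseline_stats <- function(v, rate, baseline_window) {
  n <- length(v)
  idx <- frames_in_window(seq(0, by = 1 / rate, length.out = n),
                          baseline_window[1], baseline_window[2])
  if (length(idx) < 2) {
    stop("no valid baseline segment in the requested window", call. = FALSE)
  }
  list(mean = mean(v[idx]), sd = stats::sd(v[idx]))
}

runs_to_intervals <- function(above, rate, min_duration, strict = FALSE) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & if (strict) {
    r$lengths / rate > min_duration
  } else {
    r$lengths / rate >= min_duration
  }
  tibble::tibble(start = (starts[keep] - 1) / rate, end = ends[keep] / rate)
}

#' Detect seizure-like events
#'
#' A seizure-like event (SLE) is a deviation of the membrane potential from
#' its resting value exceeding two baseline standard deviations continuously
#' for at least 5 seconds. Baseline mean and SD are taken from a configurable
#' reference segment (default: the first 10 s).
#'
#' @param vm_trace Voltage samples (mV).
#' @param rate Sampling rate (Hz).
#' @param baseline_window Reference segment `c(start, end)` in seconds.
#' @param n_sd Threshold in baseline SDs.
#' @param min_duration_s Minimum continuous duration (s).
#' @return A tibble of event intervals (`start`, `end`, seconds).
#' @export
detect_sle <- function(vm_trace, rate, baseline_window = c(0, 10),
                       n_sd = 2, min_duration_s = 5) {
  if (length(vm_trace) / rate <= min_duration_s) {
    stop("trace shorter than the minimum event duration", call. = FALSE)
  }
  bs <- baseline_stats(vm_trace, rate, baseline_window)
  above <- abs(vm_trace - bs$mean) > n_sd * bs$sd
  runs_to_intervals(above, rate, min_duration_s)
}

#' Detect network bursts
#'
#' A network burst is a depolarisation of more than 10 mV above baseline
#' lasting longer than 250 ms.
#'
#' @inheritParams detect_sle
#' @param threshold_mV Depolarisation threshold above the baseline mean (mV).
#' @return A tibble of event intervals (`start`, `end`, seconds).
#' @export
detect_network_burst <- function(vm_trace, rate, baseline_window = c(0, 10),
                                 threshold_mV = 10, min_duration_s = 0.25) {
  bs <- baseline_stats(vm_trace, rate, baseline_window)
  above <- (vm_trace - bs$mean) > threshold_mV
  runs_to_intervals(above, rate, min_duration_s, strict = TRUE)
}

overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & a_end > b_start
}

#' Select a peri-SLE probe window
#'
#' Chooses the stimulus window suitable for estimating the driving force
#' around a seizure-like event: within 15 s before SLE onset (`phase =
#' "pre"`), within 15 s of SLE cessation while inside it (`"during"`), or
#' within 15 s after cessation (`"post"`). Both the window and its immediately
#' preceding equal-length baseline must be uncontaminated by supra-threshold
#' activity (the SLEs themselves for pre/post phases, plus any intervals in
#' `contamination`, e.g. detected network bursts). Absence of a valid probe is
#' a value, not an error: a zero-row tibble is returned.
#'
#' @param stim_windows Tibble with `start`, `end` (s).
#' @param sle_intervals Tibble with `start`, `end` (s); at least one row.
#' @param phase `"pre"`, `"during"` or `"post"`.
#' @param contamination Optional tibble of intervals that must not overlap the
#'   probe or its baseline.
#' @param max_gap_s Maximum distance from the SLE boundary (s).
#' @return One row of `stim_windows` (the first valid probe) or a zero-row
#'   tibble.
#' @export
select_peri_sle_probe <- function(stim_windows, sle_intervals,
                                  phase = c("pre", "during", "post"),
                                  contamination = NULL, max_gap_s = 15) {
  phase <- match.arg(phase)
  if (nrow(sle_intervals) == 0) stop("at least one SLE required", call. = FALSE)
  stim_windows <- tibble::as_tibble(stim_windows)
  bad <- if (phase == "during") contamination else {
    dplyr::bind_rows(sle_intervals[c("start", "end")], contamination)
  }
  for (i in seq_len(nrow(stim_windows))) {
    w <- stim_windows[i, ]
    dur <- w$end - w$start
    base <- c(w$start - dur, w$start)
    ok_phase <- any(vapply(seq_len(nrow(sle_intervals)), function(j) {
      s <- sle_intervals[j, ]
      switch(phase,
        pre = w$end <= s$start && (s$start - w$end) < max_gap_s,
        during = w$start >= s$start && w$end <= s$end &&
          (s$end - w$end) < max_gap_s,
        post = w$start >= s$end && (w$start - s$end) < max_gap_s)
    }, logical(1)))
    if (!ok_phase) next
    clean <- is.null(bad) || nrow(bad) == 0 ||
      !any(overlaps(min(base[1], w$start), w$end, bad$start, bad$end))
    if (clean) return(w)
  }
  stim_windows[0, ]
}
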