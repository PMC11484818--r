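# Readers and writers: trace tables (CSV/TSV + JSON sidecar), TIFF stacks
# with label masks, parameter and protocol files, simulation export.

read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

write_config_file <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read and write model parameter files
#'
#' Parameter files are JSON or YAML (by extension) whose keys mirror the
#' arguments of [model_params()]. Unknown keys are rejected. The packaged
#' defaults live at `system.file("extdata", "pump_leak_defaults.json",
#' package = "optodf")`.
#'
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @param params A [model_params()] object.
#' @return `read_model_params()` returns a [model_params()] object;
#'   `write_model_params()` returns `path` invisibly.
#' @export
read_model_params <- function(path) {
  vals <- read_config_file(path)
  allowed <- names(formals(model_params))
  extra <- setdiff(names(vals), allowed)
  if (length(extra) > 0) {
    stop("unknown parameter keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(vals$init)) vals$init <- as.list(vals$init)
  if (!is.null(vals$constants)) {
    vals$constants <- do.call(physical_constants, as.list(vals$constants))
  }
  do.call(model_params, vals)
}

#' @rdname read_model_params
#' @export
write_model_params <- function(params, path) {
  out <- unclass(params)
  out$constants <- unclass(out$constants)
  write_config_file(out, path)
}

#' Packaged default parameter file
#'
#' @return Path to the bundled pump-leak defaults.
#' @export
default_params_file <- function() {
  system.file("extdata", "pump_leak_defaults.json", package = "optodf",
              mustWork = TRUE)
}

#' Read a stimulus protocol file
#'
#' JSON/YAML with an `events` array; each event has a `kind`
#' (`gaba_pulse`, `opto_pulse`, `param_ramp`, `param_set`) plus the arguments
#' of the corresponding constructor.
#'
#' @param path File path.
#' @return A [stim_protocol()].
#' @export
read_protocol <- function(path) {
  spec <- read_config_file(path)
  events <- spec$events
  if (is.data.frame(events)) {
    events <- lapply(seq_len(nrow(events)), function(i) {
      as.list(events[i, , drop = FALSE])
    })
  }
  built <- lapply(events, function(e) {
    e <- Filter(function(v) !is.null(v) && !is.na(v), as.list(e))
    kind <- e$kind
    e$kind <- NULL
    fn <- switch(kind,
      gaba_pulse = gaba_pulse, opto_pulse = opto_pulse,
      param_ramp = param_ramp, param_set = param_set,
      stop("unknown protocol event kind: ", kind, call. = FALSE))
    do.call(fn, e)
  })
  stim_protocol(built)
}

#' Read and write fluorescence trace tables
#'
#' Trace tables are CSV (or TSV) files with columns `time`, `roi`,
#' `background`, accompanied by an optional JSON sidecar (`<path>.json`)
#' carrying the frame rate, stimulus windows and metadata. Reading validates
#' column presence, strictly increasing time, and agreement (within 1%)
#' between the declared and inferred frame rate.
#'
#' @param path CSV/TSV path.
#' @param rec A [fluor_recording()].
#' @param sidecar Write/read the JSON sidecar.
#' @return `read_trace_table()` returns a [fluor_recording()].
#' @export
read_trace_table <- function(path, sidecar = TRUE) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  missing_cols <- setdiff(c("time", "roi", "background"), names(tab))
  if (length(missing_cols) > 0) {
    stop("trace table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  meta_path <- paste0(path, ".json")
  frame_rate <- NULL
  windows <- NULL
  metadata <- list()
  if (sidecar && file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    frame_rate <- meta$frame_rate
    if (!is.null(meta$stimulus_windows) &&
        length(meta$stimulus_windows) > 0) {
      windows <- tibble::as_tibble(meta$stimulus_windows)
    }
    metadata <- meta$metadata %||% list()
  }
  fluor_recording(tab$time, tab$roi, tab$background,
                  stimulus_windows = windows, frame_rate = frame_rate,
                  metadata = metadata)
}

#' @rdname read_trace_table
#' @export
write_trace_table <- function(rec, path, sidecar = TRUE) {
  utils::write.csv(rec$data, path, row.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(frame_rate = rec$frame_rate,
           stimulus_windows = rec$stimulus_windows,
           metadata = rec$metadata),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a multi-frame TIFF stack into a recording
#'
#' Computes the per-frame mean pixel brightness over the ROI and background
#' regions defined by a label-mask TIFF of the same frame shape (pixel value
#' `roi_label` marks the cell ROI, `background_label` the background region).
#'
#' @param path Multi-frame TIFF.
#' @param roi_mask_path Single-frame label-mask TIFF.
#' @param frame_rate Acquisition rate (Hz).
#' @param roi_label,background_label Mask values identifying the two regions.
#' @param stimulus_windows Optional stimulus windows (tibble, seconds).
#' @return A [fluor_recording()].
#' @export
read_tiff_stack <- function(path, roi_mask_path, frame_rate,
                            roi_label = 1, background_label = 2,
                            stimulus_windows = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  mask <- tiff::readTIFF(roi_mask_path, as.is = TRUE)
  if (!all(dim(frames[[1]]) == dim(mask))) {
    stop("mask shape does not match the image frames", call. = FALSE)
  }
  roi_px <- mask == roi_label
  bg_px <- mask == background_label
  if (!any(roi_px)) stop("mask contains no ROI pixels", call. = FALSE)
  if (!any(bg_px)) stop("mask contains no background pixels", call. = FALSE)
  roi <- vapply(frames, function(f) mean(f[roi_px]), numeric(1))
  bg <- vapply(frames, function(f) mean(f[bg_px]), numeric(1))
  time <- (seq_along(frames) - 0.5) / frame_rate
  fluor_recording(time, roi, bg, stimulus_windows = stimulus_windows,
                  frame_rate = frame_rate,
                  metadata = list(source = path, mask = roi_mask_path))
}

#' Export a simulation to disk
#'
#' Writes the trajectory as tidy CSV (one row per time point) and a JSON
#' metadata file (protocol events, parameters, integrator settings, package
#' version).
#'
#' @param sim An `ion_sim` from [simulate_model()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$trajectory, file.path(dir, "trajectory.csv"),
                   row.names = FALSE)
  meta <- list(
    params = unclass_params(sim$params),
    events = sim$events,
    method = sim$method,
    settings = sim$settings,
    package_version = as.character(utils::packageVersion("optodf"))
  )
  jsonlite::write_json(meta, file.path(dir, "simulation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

unclass_params <- function(params) {
  out <- unclass(params)
  out$constants <- unclass(out$constants)
  out
}
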