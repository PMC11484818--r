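#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulation
#'
#' Membrane potential together with the GABA-A, chloride and potassium
#' reversal potentials (top) and intracellular chloride (bottom).
#'
#' @param object An `ion_sim` from [simulate_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ion_sim
#' @export
autoplot.ion_sim <- function(object, ...) {
  traj <- object$trajectory
  pot <- tidyr::pivot_longer(
    traj[c("t", "Vm", "E_GABAA", "E_Cl", "E_K")],
    -"t", names_to = "potential", values_to = "mV")
  pot$panel <- "potentials (mV)"
  cl <- tibble::tibble(t = traj$t, potential = "Cl_i", mV = traj$Cl_i,
                       panel = "[Cl-]_i (mM)")
  dat <- dplyr::bind_rows(pot, cl)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t / 60, y = .data$mV,
                                    colour = .data$potential)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an in-silico experiment
#'
#' @param object A `df_experiment`.
#' @param ... Passed to [autoplot.ion_sim()].
#' @return A ggplot object with probe pulses marked.
#' @method autoplot df_experiment
#' @export
autoplot.df_experiment <- function(object, ...) {
  autoplot.ion_sim(object$sim, ...) +
    ggplot2::geom_vline(xintercept = object$report$t_pulse / 60,
                        linetype = "dashed", colour = "grey40")
}

#' Plot a fluorescence recording
#'
#' ROI and background traces with stimulus windows shaded.
#'
#' @param object A [fluor_recording()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fluor_recording
#' @export
autoplot.fluor_recording <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$data, -"time", names_to = "trace",
                             values_to = "counts")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$counts,
                                         colour = .data$trace)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time (s)", y = "photoelectrons / frame",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(object$stimulus_windows) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$stimulus_windows,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15)
  }
  p
}

#' @importFrom rlang .data
NULL
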