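#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation into long format
#'
#' @param x An `ion_sim` from [simulate_model()].
#' @param ... Unused.
#' @return A long tibble with `t`, `variable`, `value`.
#' @method tidy ion_sim
#' @export
tidy.ion_sim <- function(x, ...) {
  tidyr::pivot_longer(x$trajectory, -"t", names_to = "variable",
                      values_to = "value")
}

#' One-row summary of a simulation
#'
#' @param x An `ion_sim`.
#' @param ... Unused.
#' @return A one-row tibble with the final state, driving force and run
#'   metadata.
#' @method glance ion_sim
#' @export
glance.ion_sim <- function(x, ...) {
  fin <- x$trajectory[nrow(x$trajectory), ]
  tibble::tibble(
    duration_s = fin$t, n_steps = nrow(x$trajectory),
    Vm_final = fin$Vm, E_GABAA_final = fin$E_GABAA,
    Cl_i_final = fin$Cl_i, df_gabaa_final = fin$df_gabaa,
    method = x$method, n_events = nrow(x$events)
  )
}

#' Tidy an in-silico experiment report
#'
#' @param x A `df_experiment`.
#' @param ... Unused.
#' @return The per-pulse report tibble.
#' @method tidy df_experiment
#' @export
tidy.df_experiment <- function(x, ...) {
  x$report
}

#' One-row summary of an in-silico experiment
#'
#' @param x A `df_experiment`.
#' @param ... Unused.
#' @return A one-row tibble of baseline-to-post changes.
#' @method glance df_experiment
#' @export
glance.df_experiment <- function(x, ...) {
  r <- x$report
  b <- r[r$phase == "baseline", ]
  p <- r[r$phase == "post", ]
  tibble::tibble(
    experiment = b$experiment,
    delta_Vm = p$Vm_baseline - b$Vm_baseline,
    delta_E_GABAA = p$E_GABAA_baseline - b$E_GABAA_baseline,
    delta_Cl_i = p$Cl_i_baseline - b$Cl_i_baseline,
    delta_df_gabaa = p$df_gabaa_baseline - b$df_gabaa_baseline,
    polarity_baseline = b$polarity,
    polarity_post = p$polarity
  )
}

#' Tidy a driving-force estimate
#'
#' @param x A `df_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with `dff`, `delta_v`, `df_gabaa` and `mode`.
#' @method tidy df_estimate
#' @export
tidy.df_estimate <- function(x, ...) {
  tibble::tibble(dff = x$dff, delta_v = x$delta_v, df_gabaa = x$df_gabaa,
                 mode = x$mode)
}

#' @rdname tidy.df_estimate
#' @method glance df_estimate
#' @export
glance.df_estimate <- function(x, ...) {
  tidy.df_estimate(x)
}
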