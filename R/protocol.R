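#' Stimulus protocol events
#'
#' A stimulus protocol is an ordered list of timed interventions applied to a
#' running simulation:
#'
#' * `gaba_pulse()` - a synaptic GABA-A conductance transient (alpha
#'   function, [alpha_conductance()]);
#' * `opto_pulse()` - a square anion-conductance pulse through the GABA-A
#'   pathway, emulating activation of a light-gated anion channel;
#' * `param_ramp()` - a linear ramp of a model parameter between two times
#'   (e.g. `g_KCC2` from 20 to 0, or the impermeant-anion charge `z_i`);
#' * `param_set()` - an instantaneous parameter change.
#'
#' Rampable symbols are the scalar entries of [model_params()]
#' (`g_Na`, `g_K`, `g_Cl`, `g_HCO3`, `g_KCC2`, `P_pump`, `z_i`, and the bath
#' concentrations). Ramping `z_i` changes the average charge at fixed
#' impermeant-anion amount, so total intracellular charge shifts accordingly.
#'
#' @param t_onset,tau_ms,g_max_nS Alpha-function onset (s), time constant (ms)
#'   and peak conductance (nS).
#' @param t_start,t_end Start / end time (s).
#' @param g_nS Square-pulse conductance (nS).
#' @param symbol Name of a scalar [model_params()] entry.
#' @param from,to Ramp start and end values (interface units of the symbol).
#' @param value Value for `param_set`.
#' @param t Time of a `param_set` (s).
#' @param ... Events created by the constructors above.
#' @return `stim_protocol()` returns a list of class `stim_protocol`; the
#'   event constructors return single `protocol_event` records.
#' @name stim_protocol
NULL

#' @rdname stim_protocol
#' @export
gaba_pulse <- function(t_onset, tau_ms = 250, g_max_nS = 10) {
  structure(list(kind = "gaba_pulse", t = t_onset,
                 stim = gaba_stimulus(t_onset, tau_ms, g_max_nS)),
            class = "protocol_event")
}

#' @rdname stim_protocol
#' @export
opto_pulse <- function(t_start, t_end, g_nS = 10) {
  stopifnot(t_start < t_end, g_nS >= 0)
  structure(list(kind = "opto_pulse", t = t_start, t_start = t_start,
                 t_end = t_end, g_nS = g_nS),
            class = "protocol_event")
}

#' @rdname stim_protocol
#' @export
param_ramp <- function(symbol, from, to, t_start, t_end) {
  if (t_start >= t_end) stop("ramp requires t_start < t_end", call. = FALSE)
  structure(list(kind = "param_ramp", t = t_start, symbol = symbol,
                 from = from, to = to, t_start = t_start, t_end = t_end),
            class = "protocol_event")
}

#' @rdname stim_protocol
#' @export
param_set <- function(symbol, value, t) {
  structure(list(kind = "param_set", t = t, symbol = symbol, value = value),
            class = "protocol_event")
}

#' @rdname stim_protocol
#' @export
stim_protocol <- function(...) {
  events <- list(...)
  if (length(events) == 1 && is.list(events[[1]]) &&
      !inherits(events[[1]], "protocol_event")) {
    events <- events[[1]]
  }
  ok <- vapply(events, inherits, logical(1), "protocol_event")
  if (!all(ok)) stop("all protocol entries must be protocol events", call. = FALSE)
  events <- events[order(vapply(events, function(e) e$t, numeric(1)))]
  structure(events, class = "stim_protocol")
}

#' @export
format.stim_protocol <- function(x, ...) {
  if (length(x) == 0) return("<stim_protocol: empty>")
  lines <- vapply(unclass(x), function(e) {
    switch(e$kind,
      gaba_pulse = sprintf("gaba_pulse  t=%gs tau=%gms g_max=%gnS",
                           e$t, e$stim$tau_ms, e$stim$g_max_nS),
      opto_pulse = sprintf("opto_pulse  %g-%gs g=%gnS", e$t_start, e$t_end, e$g_nS),
      param_ramp = sprintf("param_ramp  %s %g->%g over %g-%gs",
                           e$symbol, e$from, e$to, e$t_start, e$t_end),
      param_set = sprintf("param_set   %s=%g at t=%gs", e$symbol, e$value, e$t))
  }, character(1))
  c("<stim_protocol>", paste0("  ", lines))
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Protocol event log as a tibble
#'
#' @param protocol A [stim_protocol()].
#' @return A tibble with one row per event.
#' @export
protocol_events <- function(protocol) {
  if (length(protocol) == 0) {
    return(tibble::tibble(kind = character(), t = numeric(),
                          detail = character()))
  }
  tibble::tibble(
    kind = vapply(unclass(protocol), `[[`, character(1), "kind"),
    t = vapply(unclass(protocol), `[[`, numeric(1), "t"),
    detail = format(protocol)[-1]
  )
}

# total GABA-A-pathway conductance (S) at time t from all pulse events
protocol_conductance <- function(protocol) {
  pulses <- Filter(function(e) e$kind %in% c("gaba_pulse", "opto_pulse"),
                   unclass(protocol))
  function(t) {
    g <- 0
    for (e in pulses) {
      if (e$kind == "gaba_pulse") {
        g <- g + alpha_conductance(t, e$stim)
      } else if (t >= e$t_start && t < e$t_end) {
        g <- g + e$g_nS
      }
    }
    g * 1e-9
  }
}

# piecewise value of one symbol (interface units) at time t
symbol_value <- function(events, base) {
  function(t) {
    v <- base
    for (e in events) {
      if (e$kind == "param_set") {
        if (t >= e$t) v <- e$value
      } else if (t >= e$t_end) {
        v <- e$to
      } else if (t > e$t_start) {
        v <- e$from + (e$to - e$from) * (t - e$t_start) / (e$t_end - e$t_start)
      }
    }
    v
  }
}

# map interface symbol -> (SI field, scale); bath symbols also dirty Pi_o
si_symbol_map <- list(
  g_Na = c("g_Na", 1e-2), g_K = c("g_K", 1e-2), g_Cl = c("g_Cl", 1e-2),
  g_HCO3 = c("g_HCO3", 1e-2), g_KCC2 = c("g_KCC2", 1e-2),
  P_pump = c("P", 1e2), z_i = c("z_i", 1),
  Na_o = c("Na_o", 1), K_o = c("K_o", 1), Cl_o = c("Cl_o", 1),
  HCO3_o = c("HCO3_o", 1), X_o = c("X_o", 1)
)

compile_time_varying <- function(protocol, params) {
  mods <- Filter(function(e) e$kind %in% c("param_ramp", "param_set"),
                 unclass(protocol))
  if (length(mods) == 0) return(list())
  symbols <- unique(vapply(mods, `[[`, character(1), "symbol"))
  lapply(stats::setNames(symbols, symbols), function(s) {
    if (is.null(si_symbol_map[[s]])) {
      stop("symbol `", s, "` cannot be modified by a protocol", call. = FALSE)
    }
    ev <- Filter(function(e) e$symbol == s, mods)
    ev <- ev[order(vapply(ev, `[[`, numeric(1), "t"))]
    list(field = si_symbol_map[[s]][1],
         scale = as.numeric(si_symbol_map[[s]][2]),
         value = symbol_value(ev, params[[s]]))
  })
}

# integration breakpoints implied by the protocol
protocol_breakpoints <- function(protocol, duration) {
  br <- numeric()
  dense <- list()
  for (e in unclass(protocol)) {
    if (e$kind == "gaba_pulse") {
      tail_end <- e$t + 12 * e$stim$tau_ms * 1e-3
      br <- c(br, e$t, tail_end)
      dense[[length(dense) + 1]] <- c(e$t, tail_end)
    } else if (e$kind == "opto_pulse") {
      br <- c(br, e$t_start, e$t_end)
      dense[[length(dense) + 1]] <- c(e$t_start, min(e$t_end + 1, duration))
    } else if (e$kind == "param_ramp") {
      br <- c(br, e$t_start, e$t_end)
    } else {
      br <- c(br, e$t)
    }
  }
  list(breaks = sort(unique(pmin(pmax(br, 0), duration))), dense = dense)
}
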