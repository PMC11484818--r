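#' GABA-A synaptic stimulus
#'
#' A single synaptic GABA-A conductance event: an alpha function with onset
#' `t_onset`, time constant `tau_ms` and peak conductance `g_max_nS`.
#'
#' @param t_onset Onset time (s).
#' @param tau_ms Time constant (ms).
#' @param g_max_nS Peak conductance (nS).
#' @return A list of class `gaba_stimulus`.
#' @export
gaba_stimulus <- function(t_onset, tau_ms = 250, g_max_nS = 10) {
  stopifnot(tau_ms > 0, g_max_nS >= 0)
  structure(list(t_onset = t_onset, tau_ms = tau_ms, g_max_nS = g_max_nS),
            class = "gaba_stimulus")
}

#' Alpha-function synaptic conductance
#'
#' `g(t) = g_max * ((t - t_onset)/tau) * exp(-(t - t_onset - tau)/tau)` for
#' `t > t_onset` and 0 before onset. The peak value `g_max` is reached exactly
#' one time constant after onset.
#'
#' @param t Time (s), vectorised.
#' @param stim A [gaba_stimulus()].
#' @return Conductance in nS.
#' @export
#' @examples
#' s <- gaba_stimulus(t_onset = 1, tau_ms = 250, g_max_nS = 10)
#' alpha_conductance(1.25, s)  # peak = 10 nS
alpha_conductance <- function(t, stim) {
  tau <- stim$tau_ms * 1e-3
  dt <- t - stim$t_onset
  ifelse(dt > 0, stim$g_max_nS * (dt / tau) * exp(-(dt - tau) / tau), 0)
}

#' Fraction of GABA-A current carried by chloride
#'
#' `chi = (E_HCO3 - E_GABAA) / (E_HCO3 - E_Cl)`. With instantaneous reversal
#' potentials this partition makes the total GABA-A current vanish exactly at
#' `Vm = E_GABAA`. Values outside `[0, 1]` (possible only for inconsistent
#' potentials) are clipped with a warning.
#'
#' @param E_HCO3,E_GABAA,E_Cl Reversal potentials (mV).
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' chi_fraction(-31.1, -72.8, -81.0)
chi_fraction <- function(E_HCO3, E_GABAA, E_Cl) {
  if (any(E_HCO3 == E_Cl)) {
    stop("degenerate gradients: E_HCO3 equals E_Cl, chi is undefined",
         call. = FALSE)
  }
  chi <- (E_HCO3 - E_GABAA) / (E_HCO3 - E_Cl)
  if (any(chi < 0 | chi > 1)) {
    warning("chi outside [0, 1]; clipping", call. = FALSE)
    chi <- pmin(pmax(chi, 0), 1)
  }
  chi
}

#' Chloride and bicarbonate components of the GABA-A current
#'
#' `I_Cl = chi * g * (Vm - E_Cl)` and `I_HCO3 = (1 - chi) * g * (Vm - E_HCO3)`
#' (outward-positive convention). With `chi` from [chi_fraction()] the total
#' current is zero at `Vm = E_GABAA`.
#'
#' @param Vm Membrane potential (mV).
#' @param g_now Instantaneous conductance (nS).
#' @param chi Chloride fraction of the current.
#' @param E_Cl,E_HCO3 Reversal potentials (mV).
#' @return A list with `I_Cl` and `I_HCO3` in pA (nS * mV).
#' @export
gabaa_currents <- function(Vm, g_now, chi, E_Cl, E_HCO3) {
  stopifnot(g_now >= 0)
  list(I_Cl = chi * g_now * (Vm - E_Cl),
       I_HCO3 = (1 - chi) * g_now * (Vm - E_HCO3))
}
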