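#' Carbonic acid concentration from Henry's law
#'
#' `[H2CO3] = kH * PCO2`, assuming dissolved CO2 and carbonic acid are
#' interchangeable. With the default constants (kH = 0.031 M/atm,
#' PCO2 = 0.05 atm, i.e. 5% CO2) this is 1.55 mM on both sides of the
#' membrane.
#'
#' @param PCO2 Partial pressure of CO2 (atm).
#' @param kH Henry's law constant (M/atm).
#' @return Concentration in mM.
#' @export
#' @examples
#' h2co3_concentration(0.05, 0.031)  # 1.55 mM
h2co3_concentration <- function(PCO2 = 0.05, kH = 0.031) {
  stopifnot(PCO2 >= 0, kH >= 0)
  kH * PCO2 * 1e3
}

#' Equilibrium bicarbonate from the Henderson-Hasselbalch relation
#'
#' `[HCO3-] = [H2CO3] * 10^(pH - pKa)`. At pH 7.4 and pKa 6.1 the default
#' 1.55 mM carbonic acid gives an extracellular bicarbonate of ~31 mM.
#'
#' @param h2co3 Carbonic acid concentration (mM).
#' @param pH pH at which the buffer is equilibrated.
#' @param pKa Dissociation constant of carbonic acid.
#' @return Concentration in mM.
#' @export
#' @examples
#' equilibrium_hco3(1.55, 7.4)  # ~31 mM
equilibrium_hco3 <- function(h2co3, pH, pKa = 6.1) {
  stopifnot(h2co3 >= 0)
  h2co3 * 10^(pH - pKa)
}

#' Carbonate buffer parameters
#'
#' @param PCO2,kH,pKa,Kf,Kr,pH_i,pH_o As in [model_params()].
#' @return A list of class `carbonate_params`.
#' @export
carbonate_params <- function(PCO2 = 0.05, kH = 0.031, pKa = 6.1,
                             Kf = 1e3, Kr = 2.539e9,
                             pH_i = 7.2, pH_o = 7.4) {
  stopifnot(PCO2 > 0, kH > 0, Kf > 0, Kr > 0,
            pH_i > 0, pH_i < 14, pH_o > 0, pH_o < 14)
  structure(list(PCO2 = PCO2, kH = kH, pKa = pKa, Kf = Kf, Kr = Kr,
                 pH_i = pH_i, pH_o = pH_o), class = "carbonate_params")
}

#' Net intracellular bicarbonate production rate
#'
#' Net rate of the CO2 hydration reaction,
#' `Kf*[H2CO3]_i - Kr*[H+]_i*[HCO3-]_i`, with carbonic acid clamped at its
#' Henry's-law value and `[H+]_i` fixed by the clamped intracellular pH.
#' Protons are produced (or consumed) mole-for-mole with bicarbonate; the
#' matching `h_rate` is returned alongside.
#'
#' @param hco3_i Intracellular bicarbonate (mM).
#' @param params A [carbonate_params()] object.
#' @return A list with `hco3_rate` and `h_rate` (both mM/s, equal by
#'   stoichiometry).
#' @export
#' @examples
#' carbonate_rates(9.7)$hco3_rate   # ~0: near equilibrium
carbonate_rates <- function(hco3_i, params = carbonate_params()) {
  stopifnot(hco3_i >= 0)
  h2co3 <- h2co3_concentration(params$PCO2, params$kH) * 1e-3  # M
  h_i <- 10^(-params$pH_i)                                     # M
  net <- params$Kf * h2co3 - params$Kr * h_i * (hco3_i * 1e-3) # M/s
  net <- net * 1e3                                             # mM/s
  list(hco3_rate = net, h_rate = net)
}

#' Equilibrium intracellular bicarbonate of the kinetic scheme
#'
#' The fixed point of [carbonate_rates()]: `Kf*[H2CO3]/(Kr*[H+]_i)`.
#'
#' @inheritParams carbonate_rates
#' @return Concentration in mM.
#' @export
carbonate_equilibrium_hco3 <- function(params = carbonate_params()) {
  h2co3 <- h2co3_concentration(params$PCO2, params$kH) * 1e-3
  1e3 * params$Kf * h2co3 / (params$Kr * 10^(-params$pH_i))
}

#' Na+/H+ exchanger coupling
#'
#' Every mole of H+ produced by the carbonate buffer is exported in exchange
#' for one mole of Na+ entering (1:1, electroneutral), which clamps
#' intracellular pH. The Na+ flux adjustment therefore equals the H+
#' production rate.
#'
#' @param h_production_rate H+ production rate (mM/s), signed.
#' @return Na+ influx adjustment (mM/s).
#' @export
nhe_coupling <- function(h_production_rate) {
  h_production_rate
}
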