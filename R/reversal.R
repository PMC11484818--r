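#' Nernst equilibrium potential
#'
#' Equilibrium potential of a single ionic species,
#' `E = RT/(zF) * ln(c_in/c_out)`. For a monovalent anion (valence -1) this
#' reduces to `E = RT/F * ln(c_in/c_out)`, the convention used for chloride and
#' bicarbonate throughout the model.
#'
#' @param c_in,c_out Intracellular / extracellular concentration (mM), both
#'   strictly positive.
#' @param valence Signed integer charge of the ion (non-zero).
#' @param constants A [physical_constants()] object.
#' @param species Optional name used in error messages.
#' @return Potential in mV.
#' @export
#' @examples
#' nernst_potential(5.3, 110, -1)    # E_Cl at the default steady state
#' nernst_potential(122.6, 3.5, 1)   # E_K
nernst_potential <- function(c_in, c_out, valence,
                             constants = physical_constants(),
                             species = "ion") {
  if (any(c_in <= 0)) {
    stop("non-positive intracellular concentration for ", species, call. = FALSE)
  }
  if (any(c_out <= 0)) {
    stop("non-positive extracellular concentration for ", species, call. = FALSE)
  }
  if (valence == 0) stop("valence must be non-zero", call. = FALSE)
  rtf <- constants$R * constants$T / constants$F
  # for valence -1, RT/(zF) ln(in/out) = RT/F ln(in/out) * (-1)^-1 ... keep the
  # anion-convention sign explicit: RT/(z F) ln(c_in/c_out) with z = -1 equals
  # RT/F ln(c_out/c_in); the published anion form is RT/F ln(c_in/c_out), i.e.
  # the same number. Use the general form.
  1e3 * rtf / valence * log(c_out / c_in)
}

#' GABA-A reversal potential
#'
#' Permeability-weighted (4:1 Cl-:HCO3-) reversal potential of the GABA-A
#' receptor:
#' `E_GABAA = RT/F * ln((0.8 Cl_i + 0.2 HCO3_i) / (0.8 Cl_o + 0.2 HCO3_o))`.
#' It always lies between `E_Cl` and `E_HCO3`.
#'
#' @param Cl_i,Cl_o,HCO3_i,HCO3_o Concentrations (mM), strictly positive.
#' @inheritParams nernst_potential
#' @return Potential in mV.
#' @export
#' @examples
#' gabaa_reversal(5.3, 110, 9.7, 31)
gabaa_reversal <- function(Cl_i, Cl_o, HCO3_i, HCO3_o,
                           constants = physical_constants()) {
  for (nm in c("Cl_i", "Cl_o", "HCO3_i", "HCO3_o")) {
    v <- get(nm)
    if (any(v <= 0)) stop("non-positive concentration for ", nm, call. = FALSE)
  }
  rtf <- constants$R * constants$T / constants$F
  1e3 * rtf * log((0.8 * Cl_i + 0.2 * HCO3_i) / (0.8 * Cl_o + 0.2 * HCO3_o))
}

#' All reversal potentials for a model state
#'
#' @param state An [ion_state()] (or any list with the same fields).
#' @param params A [model_params()] object supplying the bath.
#' @return A one-row tibble with `E_Cl`, `E_HCO3`, `E_K`, `E_Na`, `E_GABAA`
#'   (mV).
#' @export
reversal_potentials <- function(state, params) {
  const <- params$constants
  tibble::tibble(
    E_Cl = nernst_potential(state$Cl_i, params$Cl_o, -1, const, "Cl-"),
    E_HCO3 = nernst_potential(state$HCO3_i, params$HCO3_o, -1, const, "HCO3-"),
    E_K = nernst_potential(state$K_i, params$K_o, 1, const, "K+"),
    E_Na = nernst_potential(state$Na_i, params$Na_o, 1, const, "Na+"),
    E_GABAA = gabaa_reversal(state$Cl_i, params$Cl_o, state$HCO3_i,
                             params$HCO3_o, const)
  )
}
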