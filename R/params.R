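#' Physical constants
#'
#' Faraday constant, gas constant and absolute temperature used throughout the
#' model. Defaults correspond to physiological temperature (37 degrees C).
#'
#' @param F Faraday constant (C/mol).
#' @param R Gas constant (J/(K*mol)).
#' @param T Absolute temperature (K).
#'
#' @return A list of class `physical_constants`.
#' @export
#' @examples
#' physical_constants()
physical_constants <- function(F = 96485.33, R = 8.31446, T = 310.15) {
  stopifnot(F > 0, R > 0, T > 0)
  structure(list(F = F, R = R, T = T), class = "physical_constants")
}

#' Pump-leak model parameters
#'
#' Full parameter set of the single-compartment pump-leak model: geometry,
#' membrane capacitance, leak and KCC2 conductances, Na+/K+-ATPase pump rate,
#' water/osmotic constants, the carbonate-buffer subsystem, the GABA-A synapse,
#' and the fixed extracellular bath. All values are given in the interface
#' units noted below; internal computation is SI.
#'
#' The compartment is a cylinder (`radius_um`, `length_um`); only the lateral
#' surface carries membrane. The geometric volume (~1.96 pL for the defaults)
#' is used for simulation; `w_printed_pL` records the separately reported
#' default volume for provenance but plays no computational role.
#'
#' The `init` element holds the published default steady-state column
#' (concentrations in mM, Vm in mV). Because those values are rounded,
#' [initial_state()] refines them into an exactly charge-consistent state
#' before simulation.
#'
#' @param radius_um,length_um Compartment geometry (micrometres).
#' @param Cm Unit membrane capacitance (F/cm^2).
#' @param g_Na,g_K,g_Cl,g_HCO3 Leak conductances (uS/cm^2).
#' @param g_KCC2 KCC2 conductance (uS/cm^2).
#' @param vw Partial molar volume of water (dm^3/mol).
#' @param pw Osmotic permeability (dm/s).
#' @param P_pump ATPase pump rate constant (C/(dm^2*s)).
#' @param PCO2 Partial pressure of CO2 (atm).
#' @param kH Henry's law constant for CO2 in water (M/atm).
#' @param Kf Forward rate constant of CO2 hydration (1/s).
#' @param Kr Reverse rate constant (1/(s*M)).
#' @param pKa Dissociation constant of carbonic acid (fixed at 6.1).
#' @param g_GABAA_max Maximum GABA-A conductance (nS).
#' @param tau_ms Alpha-function time constant (ms).
#' @param pH_o,pH_i Extracellular / intracellular pH (the latter is clamped).
#' @param K_o,Na_o,Cl_o,HCO3_o,H2CO3_o,X_o Extracellular concentrations (mM).
#' @param z_o,z_i Average impermeant-anion charge outside / inside.
#' @param init Named list of initial (default steady-state) values:
#'   `K_i`, `Na_i`, `Cl_i`, `HCO3_i`, `X_i` (mM) and `Vm_mV`.
#' @param w_printed_pL Reported default compartment volume (pL), metadata only.
#' @param constants A [physical_constants()] object.
#'
#' @return A list of class `model_params`.
#' @export
#' @examples
#' p <- model_params()
#' compartment_geometry(p)
model_params <- function(radius_um = 5, length_um = 25,
                         Cm = 2e-6,
                         g_Na = 25, g_K = 70, g_Cl = 20, g_HCO3 = 4,
                         g_KCC2 = 20,
                         vw = 0.018, pw = 0.0015,
                         P_pump = 0.1,
                         PCO2 = 0.05, kH = 0.031,
                         Kf = 1e3, Kr = 2.539e9, pKa = 6.1,
                         g_GABAA_max = 10, tau_ms = 250,
                         pH_o = 7.4, pH_i = 7.2,
                         K_o = 3.5, Na_o = 145, Cl_o = 110,
                         HCO3_o = 31, H2CO3_o = 1.55, X_o = 7.5,
                         z_o = -1, z_i = -0.85,
                         init = list(K_i = 122.6, Na_i = 15, Cl_i = 5.3,
                                     HCO3_i = 9.7, X_i = 144.4,
                                     Vm_mV = -67.2),
                         w_printed_pL = 19,
                         constants = physical_constants()) {
  p <- list(radius_um = radius_um, length_um = length_um, Cm = Cm,
            g_Na = g_Na, g_K = g_K, g_Cl = g_Cl, g_HCO3 = g_HCO3,
            g_KCC2 = g_KCC2, vw = vw, pw = pw, P_pump = P_pump,
            PCO2 = PCO2, kH = kH, Kf = Kf, Kr = Kr, pKa = pKa,
            g_GABAA_max = g_GABAA_max, tau_ms = tau_ms,
            pH_o = pH_o, pH_i = pH_i,
            K_o = K_o, Na_o = Na_o, Cl_o = Cl_o, HCO3_o = HCO3_o,
            H2CO3_o = H2CO3_o, X_o = X_o, z_o = z_o, z_i = z_i,
            init = init, w_printed_pL = w_printed_pL, constants = constants)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  conds <- c("g_Na", "g_K", "g_Cl", "g_HCO3", "g_KCC2", "g_GABAA_max")
  for (g in conds) {
    if (p[[g]] < 0) stop("conductance `", g, "` must be >= 0", call. = FALSE)
  }
  concs <- c("K_o", "Na_o", "Cl_o", "HCO3_o", "H2CO3_o", "X_o")
  for (cc in concs) {
    if (p[[cc]] < 0) stop("concentration `", cc, "` must be >= 0", call. = FALSE)
  }
  for (pos in c("kH", "PCO2", "Kf", "Kr", "radius_um", "length_um",
                "Cm", "tau_ms")) {
    if (p[[pos]] <= 0) stop("parameter `", pos, "` must be > 0", call. = FALSE)
  }
  invisible(p)
}

#' Derived geometry of the model compartment
#'
#' Lateral surface area and volume of the cylindrical compartment.
#'
#' @param params A [model_params()] object.
#' @return A list with `surface_area_m2`, `volume_m3` and `volume_pL`.
#' @export
compartment_geometry <- function(params) {
  r <- params$radius_um * 1e-6
  l <- params$length_um * 1e-6
  sa <- 2 * pi * r * l
  if (sa <= 0) stop("compartment surface area is zero; check geometry", call. = FALSE)
  vol <- pi * r^2 * l
  list(surface_area_m2 = sa, volume_m3 = vol, volume_pL = vol * 1e15)
}

# Interface units -> SI used by the right-hand side. Concentrations in mM are
# numerically equal to mol/m^3 and pass through unchanged.
params_si <- function(params) {
  const <- params$constants
  geom <- compartment_geometry(params)
  list(
    F = const$F, RTF = const$R * const$T / const$F,
    SA = geom$surface_area_m2, w0 = geom$volume_m3,
    Cm = params$Cm * 1e4,                    # F/cm^2 -> F/m^2
    g_Na = params$g_Na * 1e-2,               # uS/cm^2 -> S/m^2
    g_K = params$g_K * 1e-2,
    g_Cl = params$g_Cl * 1e-2,
    g_HCO3 = params$g_HCO3 * 1e-2,
    g_KCC2 = params$g_KCC2 * 1e-2,
    P = params$P_pump * 1e2,                 # C/(dm^2 s) -> C/(m^2 s)
    pw = params$pw * 0.1,                    # dm/s -> m/s
    vw = params$vw * 1e-3,                   # dm^3/mol -> m^3/mol
    Kf = params$Kf,
    Kr = params$Kr * 1e-3,                   # 1/(s M) -> 1/(s mol/m^3)
    H2CO3_i = h2co3_concentration(params$PCO2, params$kH),
    H_i = 10^(-params$pH_i) * 1e3,           # mol/m^3
    g_gaba_max = params$g_GABAA_max * 1e-9,  # nS -> S
    tau = params$tau_ms * 1e-3,
    Na_o = params$Na_o, K_o = params$K_o, Cl_o = params$Cl_o,
    HCO3_o = params$HCO3_o, X_o = params$X_o,
    z_i = params$z_i,
    Pi_o = params$Na_o + params$K_o + params$Cl_o + params$HCO3_o + params$X_o
  )
}

#' Instantaneous state of the model compartment
#'
#' Bundles intracellular concentrations, membrane potential, volume and the
#' simulation clock into one record.
#'
#' @param Na_i,K_i,Cl_i,HCO3_i,X_i Intracellular concentrations (mM).
#' @param Vm Membrane potential (mV).
#' @param w Compartment volume (pL).
#' @param t Simulation time (s).
#' @return A one-row tibble of class `ion_state`.
#' @export
ion_state <- function(Na_i, K_i, Cl_i, HCO3_i, X_i, Vm, w, t = 0) {
  if (any(c(Na_i, K_i, Cl_i, HCO3_i, X_i) < 0)) {
    stop("intracellular concentrations must be >= 0", call. = FALSE)
  }
  if (w <= 0) stop("compartment volume must be > 0", call. = FALSE)
  out <- tibble::tibble(t = t, Na_i = Na_i, K_i = K_i, Cl_i = Cl_i,
                        HCO3_i = HCO3_i, X_i = X_i, Vm = Vm, w = w)
  class(out) <- c("ion_state", class(out))
  out
}
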