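---
title: "Modelling and optically estimating the GABA-A driving force"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and optically estimating the GABA-A driving force}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optodf)
```

The effect of opening GABA_A receptors is set by the driving force
`DF = V_m − E_GABAA`, not by chloride concentration alone: a cell can change
its [Cl⁻]ᵢ substantially while its inhibitory responses barely move, if the
membrane potential shifts along with the reversal potential. This vignette
documents the science and the design choices behind the package's four
components: the pump-leak model, the scripted manipulations of chloride
homeostasis, the fluorescence-to-driving-force pipeline, and the shot-noise
design and synthetic-data machinery that make the pipeline testable.

## The pump-leak model

A single cylindrical compartment (radius 5 µm, length 25 µm, lateral membrane
only; geometric volume ≈ 1.96 pL — a separately quoted 19 pL default is kept
as metadata `w_printed_pL` but is not used) sits in an infinite bath of fixed
composition. State variables are the intracellular amounts of Na⁺, K⁺, Cl⁻,
HCO₃⁻ and impermeant anions X (average charge `z_i = −0.85`), plus the water
volume. Fluxes are:

* **Ohmic leaks** `g_ion (V_m − E_ion)` with Nernst reversal potentials;
  conductances in µS/cm² (Na 25, K 70, Cl 20, HCO₃ 4).
* **Na⁺/K⁺-ATPase**: current density `P (Na_i/Na_o)³` (P = 0.1 C dm⁻² s⁻¹),
  exporting 3 Na⁺ per 2 K⁺ imported — the sole source of net outward charge at
  rest.
* **KCC2**: electroneutral K⁺/Cl⁻ cotransport with flux
  `g_KCC2 (E_K − E_Cl)`; at the default 20 µS/cm² it holds E_Cl ≈ 14 mV below
  V_m, which is what makes resting GABA responses hyperpolarizing.
* **GABA_A receptors**: an alpha-function conductance
  `g(t) = g_max (t/τ) e^{−(t−τ)/τ}` (τ = 250 ms, g_max = 10 nS) split between
  Cl⁻ and HCO₃⁻ by the fraction `χ = (E_HCO3 − E_GABAA)/(E_HCO3 − E_Cl)`,
  recomputed each step from the instantaneous potentials so the summed current
  reverses exactly at E_GABAA. Overlapping events sum.
* **Carbonate buffering**: [H₂CO₃] is clamped at its Henry's-law value
  (0.031 M/atm × 0.05 atm = 1.55 mM, assumed equilibrated across the
  membrane), and intracellular HCO₃⁻ follows
  `K_f [H₂CO₃] − K_r [H⁺] [HCO₃⁻]` with K_f = 10³ s⁻¹,
  K_r = 2.539 × 10⁹ M⁻¹s⁻¹. At pH 7.2 the relaxation rate K_r[H⁺] ≈ 160 s⁻¹,
  so [HCO₃⁻]ᵢ is effectively chemically clamped near
  K_f[H₂CO₃]/(K_r[H⁺]) ≈ 9.68 mM. Every proton produced is exchanged 1:1 for
  Na⁺ (electroneutral NHE), which is how intracellular pH stays at 7.2
  exactly.
* **Osmosis**: `dw/dt = p_w v_w SA (Π_i − Π_o)` over all solutes; the default
  intra- and extracellular compositions both sum to 297 mM.

**Membrane potential is algebraic, not integrated**:
`V_m = F w Σ z_i c_i / (C_m SA)`. This charge-difference formulation ties V_m
bit-for-bit to the ion bookkeeping — an error in any flux stoichiometry shows
up immediately as a voltage drift, and the identity
`F · d(Σ z_i n_i)/dt = −I_membrane` holds exactly (it is tested).

### Units, initialization and integration

Interfaces use mM, mV, pL, s, µS/cm², nS; internals are SI (mol/m³ is
numerically equal to mM, which keeps the two readable against each other).
The published default concentrations are rounded to 0.1 mM, which is far too
coarse for a charge-difference model: 0.1 mM of net charge corresponds to
over a volt. `initial_state()` therefore refines X_i (by ~0.16 mM) so the net
charge reproduces the −67.2 mV default exactly at the geometric volume;
`steady_state()` then integrates for an hour of simulated time and polishes
the fixed point with a damped Newton iteration on the full right-hand side
(residuals typically < 10⁻¹² s⁻¹). From the published defaults this lands at
V_m −67.22 mV, Cl⁻ 5.28 mM, K⁺ 122.64 mM, HCO₃⁻ 9.68 mM — the published
steady-state column within its own rounding.

The production integrator is `deSolve::lsoda` (rtol = atol = 10⁻⁸), run
piecewise between protocol breakpoints so conductance pulses and ramps are
never stepped over, with a 50 ms step cap inside conductance events. The
carbonate term (160 s⁻¹) and the membrane charge relaxation during a 10 nS
pulse (C_m/g ≈ 1.6 ms) make the system stiff, which is why the default is an
implicit adaptive scheme. A fixed-step RK4 reference integrator
(`step_state()`, `simulate_model(method = "rk4")`) exists for cross-checks;
the two agree to < 10⁻⁶ relative on a mixed ramp-plus-pulse protocol at
dt = 1 ms. Any step producing a negative concentration raises an error asking
for a smaller dt rather than silently clipping.

## The in-silico experiments

`kcc2_block_experiment()` probes the cell with a synaptic pulse at 40 min,
ramps `g_KCC2` 20 → 0 µS/cm² over minutes 41–50 (a ramp rather than a step,
mirroring a pharmacological wash-in; a test verifies ramp and step reach the
same endpoint), re-equilibrates, and probes again at 70 min. Chloride rises
from 5.28 to 9.62 mM, E_GABAA climbs ~12 mV against ~3 mV of V_m change, and
the response polarity flips. Restoring the conductance returns every state
variable to within 1% (washout). Pulse times are configurable; the defaults
place them comfortably outside the manipulation window.

`impermeant_anion_experiment()` ramps the average impermeant charge `z_i`
from −0.85 to −1.05 over the same window **at fixed impermeant amount**: the
ramp changes total intracellular charge, the membrane fluxes compensate, and
the system settles with V_m and E_Cl shifted down together, chloride reduced,
and volume up ~10%. The alternative semantics (injecting additional charged
molecules) would change the conserved X amount and thus the fixed point
itself; fixed amount is the cleaner "pure charge" manipulation and is the
package's choice.

One quantitative subtlety is worth recording. Because [HCO₃⁻]ᵢ is chemically
clamped, E_HCO3 is effectively constant, so E_GABAA follows the z-shift only
through its 0.8-weighted chloride term while V_m tracks E_Cl. In the
converged run, ΔV_m = −2.36 mV, ΔE_Cl = −2.62 mV (|ΔDF_Cl|/|ΔE_Cl| ≈ 0.10),
but ΔE_GABAA = −1.77 mV, so the driving-force change measured against
E_GABAA is ~33% of ΔE_GABAA rather than under 20%. The "V_m and the reversal
move in tandem" picture is exact for chloride and diluted for the mixed
GABA_A reversal in any model with a clamped bicarbonate pool. The simulated
GABA responses before and after the shift still differ by only ~10% in
amplitude with unchanged polarity.

## The trace-analysis pipeline

`estimate_df_gabaa()` composes, in order: background subtraction (the
background ROI smoothed with a centred 100-frame moving average for
all-optical recordings, raw for puff recordings); least-squares polynomial
detrending (order 9 by default, 10 allowed — an explicit setting, not
automatic selection) fitted only to samples outside the stimulus windows
(padded by 0.5 s to keep response tails out of the fit); then one of three
ΔF/F₀ readouts:

* **epoch average** — the stimulation epochs and the equal-length baselines
  immediately preceding each are averaged sample-wise before a mean-mode
  ΔF/F₀ is taken;
* **extremum** — for single agonist-puff responses, the most-deviating sample
  of the 7-frame-smoothed trace against the pre-stimulus baseline mean
  (deviation magnitude decides between maximum and minimum, since response
  polarity is exactly what is being measured);
* **in-vivo** — single stimulus window versus an equal flank (preceding by
  default), with the same contrast computed on the background trace
  subtracted to cancel shared neuropil contamination.

Detrending makes the trace zero-mean, so the ΔF/F₀ denominator F₀ is taken
from the background-corrected (not detrended) baseline frames — otherwise the
ratio would be ill-defined. All windows are half-open `[start, end)` in
seconds; frames are timestamped at exposure start.

ΔF/F₀ converts to voltage through a linear calibration. The bundled default
slope is 0.1845% per mV with fluorescence increasing on hyperpolarization,
i.e. 5.42 mV per ΔF/F₀ percent; calibrations for other dyes are supplied by
the user. Internally the driving force is `DF = V_m − E_GABAA`, which is
positive at the default steady state where GABA hyperpolarizes; the optical
measurement is the voltage shift toward E_GABAA, so the estimator returns
`DF = −ΔV`, and `df_as_shift()` gives the measured-shift presentation
(negative for hyperpolarizing responses) used when comparing against
shift-convention reports.

## Shot-noise design and the synthetic generator

The acquisition calculator implements the photon-budget chain: electrons per
frame = well depth / quantum efficiency (30000/0.82 = 36585.37), required
baseline photons `F₀ = (SNR/ΔF/F₀)²` (10⁶ for SNR 10 at 1%), frames required
(≈ 27), and the per-stimulation SNR `ΔF/F₀ · √(epf · rate · duration)` (≈ 9.6
for 1 s and ≈ 13.5 for 2 s at 25 Hz). Dark and read noise are excluded by
assumption; `predicted_df_sd()` adds only the baseline-period Poisson term
and background photons.

Those formulas deliberately ignore the analysis pipeline. Because every
pipeline stage is linear in photon counts, `pipeline_df_sd()` instead
propagates the per-frame Poisson variances exactly through the
background-smoothing and detrend operators. This matters: interpolating a
9th-order polynomial across the five excluded stimulation windows amplifies
the estimator's shot noise roughly eleven-fold over the naive bound (2.82 mV
predicted vs 0.26 mV naive at the default budget; a 200-seed Monte-Carlo
gives 2.96 mV, 5% from the propagated prediction). Low-order detrending is
statistically cheaper whenever the bleach is genuinely smooth.

`synth_scenario()`/`render_recording()` generate ground-truth-labelled
recordings: five 2 s stimulation epochs every 5 s in a 25 s, 25 Hz recording
at 36585 photoelectrons per frame; V_m relaxes exponentially toward
`rest − DF` during each epoch (τ = 50 ms by default, 500 ms as an
astrocyte-like preset — presets, not measured constants) or, in mechanistic
mode, comes from the pump-leak model under square anion-conductance pulses;
fluorescence is linear in voltage with monoexponential bleaching (5% per
25 s, chosen so the 9th-order detrend is genuinely exercised); the background
trace carries its own shot noise, optional shared artefacts, and optional
seizure-like excursions. Manifests record every generative parameter, the
per-epoch true ΔF/F₀ and ΔV, and the seed; analysis never reads them.

The generator emulates the statistical structure the pipeline assumes —
linear gain, Poisson noise, smooth bleach, additive background — and not
optics: no point-spread function, no motion, no dye photophysics beyond the
single bleach exponential, no spike-shaped transients. Passing round-trip
tests therefore validates the pipeline's arithmetic and noise behaviour, not
its robustness to motion artefacts or segmentation errors in real movies.

## Numerical and testing choices

* Round-trip accuracy is asserted with near-instantaneous voltage kinetics
  (τ = 2 ms): with the default τ = 50 ms the epoch mean provably sits τ/T
  (2.5%) below the plateau, a kinetics bias rather than a pipeline error.
  At τ = 2 ms imposed driving forces of −15…+15 mV are recovered within
  0.1 mV.
* Event rules are boundary-tested on constructed traces: a 4 s excursion is
  not a seizure-like event, 10 s is; 9 mV or 200 ms depolarisations are not
  network bursts, 12 mV for 400 ms is; exactly 250 ms is excluded (the rule
  is strictly "longer than").
* Test problem sizes: hour-scale model runs for steady states, 75–110 min
  for the two experiments, 200 Monte-Carlo seeds for the noise comparison —
  sizes at which every asserted quantity is converged (the z-shift endpoint,
  for example, is identical at 70 and 240 simulated minutes).
* Degenerate inputs fail loudly: non-positive concentrations in Nernst
  ratios, equal E_Cl and E_HCO3 in χ, zero baselines in ΔF/F₀,
  underdetermined polynomial fits, negative concentrations under too-large
  fixed steps, single-frame recordings without a declared frame rate.

## Limitations

A single compartment with an infinite bath: no dendrites, no
action-potential conductances, no extracellular accumulation, no explicit
carbonic-anhydrase kinetics or intracellular pH dynamics beyond the clamp.
The imaging model omits optics and motion entirely. The in-vivo ΔF/F₀ uses
the ROI flank mean (signal plus any residual background) as F₀; when
background contamination is a large fraction of the ROI fluorescence this
compresses estimates proportionally, which is inherent to the
neuropil-corrected readout rather than to this implementation.
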