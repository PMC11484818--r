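Package: optodf
Title: Pump-Leak Modelling and All-Optical Estimation of GABA-A Receptor Driving Force
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the chloride/bicarbonate driving force across
    GABA-A receptors (DF = Vm - E_GABAA) in single cells. Implements a
    single-compartment pump-leak biophysical model of Na+, K+, Cl-, HCO3-,
    impermeant anions, membrane potential and volume (leak channels,
    Na+/K+-ATPase, KCC2, GABA-A receptors, carbonate buffering with Na+/H+
    exchange); scripted in-silico experiments (KCC2 block, impermeant-anion
    charge shift); a fluorescence trace-analysis pipeline that converts
    voltage-indicator dF/F0 measurements into driving-force estimates; a
    photon shot-noise acquisition-design calculator; and a synthetic
    voltage-imaging generator with ground-truth manifests for end-to-end
    validation without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
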