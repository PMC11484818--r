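{
  "radius_um": 5,
  "length_um": 25,
  "Cm": 2e-06,
  "g_Na": 25,
  "g_K": 70,
  "g_Cl": 20,
  "g_HCO3": 4,
  "g_KCC2": 20,
  "vw": 0.018,
  "pw": 0.0015,
  "P_pump": 0.1,
  "PCO2": 0.05,
  "kH": 0.031,
  "Kf": 1000,
  "Kr": 2539000000,
  "pKa": 6.1,
  "g_GABAA_max": 10,
  "tau_ms": 250,
  "pH_o": 7.4,
  "pH_i": 7.2,
  "K_o": 3.5,
  "Na_o": 145,
  "Cl_o": 110,
  "HCO3_o": 31,
  "H2CO3_o": 1.55,
  "X_o": 7.5,
  "z_o": -1,
  "z_i": -0.85,
  "init": {
    "K_i": 122.6,
    "Na_i": 15,
    "Cl_i": 5.3,
    "HCO3_i": 9.7,
    "X_i": 144.4,
    "Vm_mV": -67.2
  },
  "w_printed_pL": 19
}
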