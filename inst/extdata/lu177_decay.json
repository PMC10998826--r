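{
  "_comment": [
    "Lu-177 decay data, version 1. Values rounded from published open",
    "nuclear-data compilations (DDEP/ICRP-107-style recommended data).",
    "Beta branches are represented as mean-energy lines (E_keV = branch",
    "mean beta energy, yield = branch probability); conversion and Auger",
    "electrons as discrete lines; photons include gammas and Hf K/L",
    "fluorescence X-rays (Kalpha/Kbeta grouped, L X-rays as one line).",
    "Yield-weighted electron energy of this table: 146.19 keV per decay.",
    "Half-life 6.647 d = 574,300.8 s."
  ],
  "nuclide": "Lu-177",
  "version": 1,
  "half_life_s": 574300.8,
  "electrons": [
    {"E_keV": 149.1,  "yield": 0.794,   "kind": "beta_mean"},
    {"E_keV": 111.7,  "yield": 0.090,   "kind": "beta_mean"},
    {"E_keV": 67.9,   "yield": 0.0005,  "kind": "beta_mean"},
    {"E_keV": 47.66,  "yield": 0.1161,  "kind": "beta_mean"},
    {"E_keV": 47.60,  "yield": 0.100,   "kind": "ce_K_113"},
    {"E_keV": 102.3,  "yield": 0.042,   "kind": "ce_L_113"},
    {"E_keV": 110.7,  "yield": 0.012,   "kind": "ce_MN_113"},
    {"E_keV": 143.0,  "yield": 0.0050,  "kind": "ce_K_208"},
    {"E_keV": 198.1,  "yield": 0.0009,  "kind": "ce_L_208"},
    {"E_keV": 45.7,   "yield": 0.0053,  "kind": "auger_K"},
    {"E_keV": 5.8,    "yield": 0.120,   "kind": "auger_L"}
  ],
  "photons": [
    {"E_keV": 208.37, "yield": 0.1038,  "kind": "gamma"},
    {"E_keV": 112.95, "yield": 0.0620,  "kind": "gamma"},
    {"E_keV": 321.32, "yield": 0.00216, "kind": "gamma"},
    {"E_keV": 249.67, "yield": 0.00212, "kind": "gamma"},
    {"E_keV": 71.64,  "yield": 0.00154, "kind": "gamma"},
    {"E_keV": 55.79,  "yield": 0.0245,  "kind": "xray_Ka1"},
    {"E_keV": 54.61,  "yield": 0.0142,  "kind": "xray_Ka2"},
    {"E_keV": 63.2,   "yield": 0.0090,  "kind": "xray_Kb"},
    {"E_keV": 8.0,    "yield": 0.0150,  "kind": "xray_L"}
  ]
}
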