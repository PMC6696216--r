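{
  "comment": "Reference values for the five virotoxin peptides of Amanita virosa (MN12SX/Def2TZVP/H2O frontier energies and published descriptor tables).",
  "frontier": [
    {"label": "Alaviroidin",   "epsilon_homo": -6.072, "epsilon_lumo": -1.700, "unit": "ev"},
    {"label": "Deoxoviroidin", "epsilon_homo": -5.929, "epsilon_lumo": -1.467, "unit": "ev"},
    {"label": "Deoxoviroisin", "epsilon_homo": -5.681, "epsilon_lumo": -1.228, "unit": "ev"},
    {"label": "Viroidin",      "epsilon_homo": -6.056, "epsilon_lumo": -1.622, "unit": "ev"},
    {"label": "Viroisin",      "epsilon_homo": -5.888, "epsilon_lumo": -1.593, "unit": "ev"}
  ],
  "expected_global": {
    "Alaviroidin":   {"gap": 4.372, "lambda_max": 284, "chi": 3.886, "eta": 4.372, "omega": 1.727, "omega_minus": 5.670, "omega_plus": 1.784, "net_electrophilicity": 7.454, "pka": 12.69},
    "Deoxoviroidin": {"gap": 4.462, "lambda_max": 278, "chi": 3.698, "eta": 4.462, "omega": 1.533, "omega_minus": 5.193, "omega_plus": 1.495, "net_electrophilicity": 6.688, "pka": 12.62},
    "Deoxoviroisin": {"gap": 4.453, "lambda_max": 278, "chi": 3.454, "eta": 4.453, "omega": 1.340, "omega_minus": 4.685, "omega_plus": 1.231, "net_electrophilicity": 5.916, "pka": 12.63},
    "Viroidin":      {"gap": 4.434, "lambda_max": 280, "chi": 3.839, "eta": 4.434, "omega": 1.662, "omega_minus": 5.520, "omega_plus": 1.682, "net_electrophilicity": 7.202, "pka": 12.64},
    "Viroisin":      {"gap": 4.295, "lambda_max": 289, "chi": 3.740, "eta": 4.295, "omega": 1.629, "omega_minus": 5.396, "omega_plus": 1.655, "net_electrophilicity": 7.051, "pka": 12.76}
  },
  "pka_labels": {
    "comment": "The published pKa table carries residue-style labels that do not name the peptides; rows map to molecules in descriptor-table row order, verified by pKa = 16.3088 - 0.8268*eta at 2 decimals for every row.",
    "labels":    ["FAR", "FAY", "FVY", "FWC", "FWY"],
    "molecules": ["Alaviroidin", "Deoxoviroidin", "Deoxoviroisin", "Viroidin", "Viroisin"],
    "pka":       [12.69, 12.62, 12.63, 12.64, 12.76]
  },
  "site_blocks": {
    "comment": "Extreme-site local descriptors: dual_scaled is 100 x the condensed dual descriptor; parr_plus/parr_minus are radical-anion/cation Mulliken spin densities.",
    "Alaviroidin": [
      {"atom_index": 50, "element": "C", "dual_scaled": 8.71,   "parr_plus": 0.227, "parr_minus": 0.007},
      {"atom_index": 24, "element": "N", "dual_scaled": -13.59, "parr_plus": 0.048, "parr_minus": 0.275}
    ],
    "Deoxoviroidin": [
      {"atom_index": 1,  "element": "S", "dual_scaled": 6.43,   "parr_plus": 0.071, "parr_minus": 0.010},
      {"atom_index": 48, "element": "C", "dual_scaled": -11.44, "parr_plus": 0.103, "parr_minus": 0.358}
    ],
    "Deoxoviroisin": [
      {"atom_index": 59, "element": "C", "dual_scaled": 12.91,  "parr_plus": 0.259, "parr_minus": 0.067},
      {"atom_index": 49, "element": "C", "dual_scaled": -15.01, "parr_plus": 0.058, "parr_minus": 0.386}
    ],
    "Viroidin": [
      {"atom_index": 50, "element": "C", "dual_scaled": 7.07,   "parr_plus": 0.268, "parr_minus": 0.045},
      {"atom_index": 24, "element": "N", "dual_scaled": -10.04, "parr_plus": 0.050, "parr_minus": 0.225}
    ],
    "Viroisin": [
      {"atom_index": 1,  "element": "S", "dual_scaled": 7.83,   "parr_plus": 0.086, "parr_minus": 0.005},
      {"atom_index": 25, "element": "N", "dual_scaled": -9.77,  "parr_plus": 0.044, "parr_minus": 0.206}
    ]
  }
}
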