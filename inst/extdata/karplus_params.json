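{
  "comment": "Named Karplus parameter sets (Hz) and the proton-torsion map relating each coupled fragment to its governing torsion. J(phi) = A*cos^2(phi) + B*cos(phi) + C + sum_i dchi_i*(D_i + E_i*cos^2(xi_i*phi + F_i*|dchi_i|)). Generalized H-C-C-H coefficients follow the Haasnoot-de Leeuw-Altona lineage; H-C-O-P and C-C-O-P sets follow the Lankhorst/Plavec-Chattopadhyaya phosphate parametrizations. Group electronegativities: O 1.27, N 0.85, C 0.68; orientation signs xi are idealized beta-D-ribonucleoside defaults.",
  "karplus_sets": {
    "hh_H1'H2'": {
      "A": 13.7, "B": -0.73, "C": 0.0,
      "substituent_terms": [
        {"dchi": 1.27, "xi": -1, "D": 0.56, "E": -2.47, "F": 16.9},
        {"dchi": 0.85, "xi":  1, "D": 0.56, "E": -2.47, "F": 16.9},
        {"dchi": 1.27, "xi":  1, "D": 0.56, "E": -2.47, "F": 16.9},
        {"dchi": 0.68, "xi": -1, "D": 0.56, "E": -2.47, "F": 16.9}
      ]
    },
    "hh_H2'H3'": {
      "A": 13.7, "B": -0.73, "C": 0.0,
      "substituent_terms": [
        {"dchi": 1.27, "xi": -1, "D": 0.56, "E": -2.47, "F": 16.9},
        {"dchi": 0.68, "xi":  1, "D": 0.56, "E": -2.47, "F": 16.9},
        {"dchi": 1.27, "xi":  1, "D": 0.56, "E": -2.47, "F": 16.9},
        {"dchi": 0.68, "xi": -1, "D": 0.56, "E": -2.47, "F": 16.9}
      ]
    },
    "hh_H3'H4'": {
      "A": 13.7, "B": -0.73, "C": 0.0,
      "substituent_terms": [
        {"dchi": 1.27, "xi": -1, "D": 0.56, "E": -2.47, "F": 16.9},
        {"dchi": 0.68, "xi":  1, "D": 0.56, "E": -2.47, "F": 16.9},
        {"dchi": 1.27, "xi":  1, "D": 0.56, "E": -2.47, "F": 16.9},
        {"dchi": 0.68, "xi": -1, "D": 0.56, "E": -2.47, "F": 16.9}
      ]
    },
    "hh_gamma": {"A": 10.2, "B": -0.8, "C": 0.0},
    "hcop": {"A": 15.3, "B": -6.1, "C": 1.6},
    "ccop": {"A": 6.9, "B": -3.4, "C": 0.7}
  },
  "proton_torsion_map": {
    "H1'H2'":  {"governing": "nu1",     "slope": 1.03, "offset": 121.4,  "set": "hh_H1'H2'"},
    "H2'H3'":  {"governing": "nu2",     "slope": 1.06, "offset": 2.4,    "set": "hh_H2'H3'"},
    "H3'H4'":  {"governing": "nu3",     "slope": 1.06, "offset": -124.0, "set": "hh_H3'H4'"},
    "H4'H5'":  {"governing": "gamma",   "slope": 1.0,  "offset": 0.0,    "set": "hh_gamma"},
    "H4'H5''": {"governing": "gamma",   "slope": 1.0,  "offset": -120.0, "set": "hh_gamma"}
  },
  "backbone_fragment_map": {
    "H5'P":  {"governing": "beta",    "offset": 120.0,  "set": "hcop"},
    "H5''P": {"governing": "beta",    "offset": -120.0, "set": "hcop"},
    "C4'Pb": {"governing": "beta",    "offset": 0.0,    "set": "ccop"},
    "H3'P":  {"governing": "epsilon", "offset": -120.0, "set": "hcop"},
    "C2'P":  {"governing": "epsilon", "offset": 120.0,  "set": "ccop"},
    "C4'Pe": {"governing": "epsilon", "offset": 0.0,    "set": "ccop"}
  },
  "annotation_fragments": ["4JH4'P", "4JH5'P", "4JH5''P"]
}
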