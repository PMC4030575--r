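{
  "comment": "Experimentally determined rate constants for the E. coli DnaK/DnaJ system. Units: s^-1 for first-order rates, M^-1 s^-1 for binding rates, M for concentrations. k_h_S is the maximal DnaJ-stimulated hydrolysis rate (acceleration 3000 over basal). Pool fixes [ATP]/[ADP] = 10.",
  "micro_apo": {
    "k_ATP_minus": 1.33e-4,
    "k_ATP_plus": 1.3e5,
    "k_ADP_minus": 0.022,
    "k_ADP_plus": 2.67e5
  },
  "substrate": {
    "k_on_ATP": 4.5e5,
    "k_off_ATP": 2,
    "k_on_ADP": 1000,
    "k_off_ADP": 4.7e-4
  },
  "hydrolysis": {
    "k_h": 6e-4,
    "k_h_S": 1.8,
    "k_synth": 0
  },
  "pool": {
    "ATP": 1e-3,
    "ADP": 1e-4
  }
}
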