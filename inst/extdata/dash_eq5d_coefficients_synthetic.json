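{
  "provenance": "synthetic placeholder: qualitative structure of a mapping estimated on an upper-limb fracture population (pain worsens the index, better function and pre-injury health improve it); values are not estimates from any published regression",
  "intercept": 0.08,
  "beta_eq5d_pre": 0.55,
  "beta_dash_pain": -0.0035,
  "beta_eq5d_function": 0.40,
  "beta_interaction": -0.0012
}
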