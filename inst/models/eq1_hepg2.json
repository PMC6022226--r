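{
  "endpoint": "HepG2",
  "intercept": -0.7926,
  "terms": [
    {"descriptor": "CHI_3_C", "coefficient": -1.598},
    {"descriptor": "Dipole_Y", "coefficient": 0.2775},
    {"descriptor": "Jurs_PNSA_3", "coefficient": -0.03102},
    {"descriptor": "Shadow_YZ", "coefficient": 0.04829}
  ]
}
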