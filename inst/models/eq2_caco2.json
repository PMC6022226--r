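{
  "endpoint": "Caco-2",
  "intercept": -6.6095,
  "terms": [
    {"descriptor": "IAC_Mean", "coefficient": -3.7896},
    {"descriptor": "Dipole_X", "coefficient": 0.11713},
    {"descriptor": "Shadow_Ylength", "coefficient": -0.1615}
  ]
}
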