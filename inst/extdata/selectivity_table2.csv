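compound,ic50_wi38_um,se_wi38,ic50_hepg2_um,se_hepg2,selectivity_index
13a,73.20,3.47,3.48,0.28,21
15a,55.92,0.39,5.03,0.39,11
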