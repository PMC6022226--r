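condition,percent_positive
control,1.75
13a,13.76
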