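compound,cell_line,experimental,predicted,residual
6,Caco-2,-1.9114,-1.8158,-0.0956
9,Caco-2,-2.3424,-1.7150,-0.6275
13a,Caco-2,-1.0052,-1.7283,0.7231
6,HepG2,-1.4086,-0.9815,-0.4271
8d,HepG2,-1.9538,-1.9191,-0.0347
15a,HepG2,-0.7016,-0.8816,0.1801
15c,HepG2,-0.8791,-1.1608,0.2817
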