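compound,cell_line,experimental,predicted,residual
4a,Caco-2,-2.2849,-2.2003,-0.0845
4b,Caco-2,-1.8253,-2.0638,0.2385
8a,Caco-2,-0.9309,-0.8882,-0.0427
8b,Caco-2,-1.9523,-1.9601,0.0078
8c,Caco-2,-1.8861,-1.8261,-0.0600
8d,Caco-2,-1.2047,-1.1348,-0.0699
11b,Caco-2,-2.1627,-2.1391,-0.0237
11c,Caco-2,-2.0351,-2.0812,0.0462
11d,Caco-2,-1.2058,-1.5517,0.3459
13a,Caco-2,-1.9213,-1.8689,-0.0524
13b,Caco-2,-1.9852,-1.7932,-0.1920
15a,Caco-2,-2.1997,-2.1829,-0.0168
15b,Caco-2,-2.2428,-2.1671,-0.0757
15c,Caco-2,-1.6633,-1.6425,-0.0208
4a,HepG2,-1.5500,-1.5052,-0.0447
4b,HepG2,-0.9074,-0.9211,0.0137
8a,HepG2,-1.4312,-1.5247,0.0935
8b,HepG2,-1.0734,-1.0444,-0.0290
8c,HepG2,-1.4742,-1.6672,0.1930
9,HepG2,-2.2123,-2.1558,-0.0565
11a,HepG2,-2.3118,-2.1523,-0.1595
11b,HepG2,-1.7349,-1.9201,0.1852
11c,HepG2,-1.8603,-1.9921,0.1317
11d,HepG2,-2.3222,-2.2134,-0.1088
13a,HepG2,-0.5416,-0.6399,0.0983
13b,HepG2,-1.0719,-1.0082,-0.0637
15b,HepG2,-1.3992,-1.1459,-0.2533
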