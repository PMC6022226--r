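O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(cc1)S(N)(=O)=O	4a
O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(cc1)S(=O)(=O)Nc1ccccn1	4b
O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(cc1)C(C)=O	6
O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(cc1)C(C)=NNc1ccccc1	8a
O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(cc1)C(C)=NNc1ccc(cc1[N+](=O)[O-])[N+](=O)[O-]	8b
O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(cc1)C(C)=NNc1c(Cl)cc(Cl)cc1Cl	8c
O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(cc1)C(C)=NNS(=O)(=O)c1ccc(C)cc1	8d
O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(cc1)C(C)=NNC(N)=S	9
O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(cc1)C(C)=NNc1nc(C)cs1	11a
O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(cc1)C(C)=NNc1nc(C)c(s1)C(=O)OCC	11b
O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(cc1)C(C)=NNc1nc(C)c(s1)N=Nc1ccc(Cl)cc1	11c
O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(cc1)C(C)=NNc1nc(C)c(s1)N=Nc1ccc(C)cc1	11d
O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(cc1)C(C)=NNc1nc(cs1)-c1ccccc1	13a
O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(cc1)C(C)=NNc1nc(cs1)-C1=Cc2ccccc2OC1=O	13b
O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(cc1)C(C)=NNC1=NCC(=O)S1	15a
O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(cc1)C(C)=NNC1=NC(C)C(=O)S1	15b
O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(cc1)C(C)=NNC1=NC(=O)C(CC(=O)O)S1	15c
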