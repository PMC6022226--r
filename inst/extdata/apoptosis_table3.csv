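compound,marker,unit,level,fold_of_control
13a,caspase3,ng/mg protein,0.3021,6.6
13a,bax,pg/mg protein,453.3,16.5
13a,bcl2,ng/mg protein,1.51,0.21
15a,caspase3,ng/mg protein,0.2625,5.7
15a,bax,pg/mg protein,394.3,14.3
15a,bcl2,ng/mg protein,2.73,0.39
control,caspase3,ng/mg protein,0.0457,NA
control,bax,pg/mg protein,27.52,NA
control,bcl2,ng/mg protein,7.07,NA
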