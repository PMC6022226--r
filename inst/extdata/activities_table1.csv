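compound,cell_line,ic50_um,se,censored
4a,HepG2,35.48,2.93,FALSE
4a,MCF7,50.73,4.61,FALSE
4a,Caco-2,192.69,15.33,FALSE
4b,HepG2,8.08,0.51,FALSE
4b,MCF7,22.95,2.04,FALSE
4b,Caco-2,66.88,6.07,FALSE
6,HepG2,25.62,1.36,FALSE
6,MCF7,NA,NA,TRUE
6,Caco-2,81.54,6.89,FALSE
8a,HepG2,26.99,2.01,FALSE
8a,MCF7,14.30,1.18,FALSE
8a,Caco-2,8.53,0.72,FALSE
8b,HepG2,11.84,1.34,FALSE
8b,MCF7,126.08,10.87,FALSE
8b,Caco-2,89.59,7.26,FALSE
8c,HepG2,29.80,2.21,FALSE
8c,MCF7,NA,NA,TRUE
8c,Caco-2,76.93,6.59,FALSE
8d,HepG2,89.91,7.63,FALSE
8d,MCF7,NA,NA,TRUE
8d,Caco-2,16.02,1.32,FALSE
9,HepG2,163.03,10.22,FALSE
9,MCF7,NA,NA,TRUE
9,Caco-2,NA,NA,TRUE
11a,HepG2,NA,NA,TRUE
11a,MCF7,13.86,1.19,FALSE
11a,Caco-2,10.12,0.90,FALSE
11b,HepG2,54.31,3.87,FALSE
11b,MCF7,63.42,5.69,FALSE
11b,Caco-2,145.46,8.02,FALSE
11c,HepG2,72.50,6.33,FALSE
11c,MCF7,34.73,2.94,FALSE
11c,Caco-2,108.41,11.36,FALSE
11d,HepG2,NA,NA,TRUE
11d,MCF7,NA,NA,TRUE
11d,Caco-2,16.06,1.28,FALSE
13a,HepG2,3.48,0.28,FALSE
13a,MCF7,83.23,6.85,FALSE
13a,Caco-2,83.43,7.04,FALSE
13b,HepG2,11.80,1.16,FALSE
13b,MCF7,NA,NA,TRUE
13b,Caco-2,96.64,5.37,FALSE
15a,HepG2,5.03,0.39,FALSE
15a,MCF7,10.95,0.96,FALSE
15a,Caco-2,158.38,9.39,FALSE
15b,HepG2,25.07,2.08,FALSE
15b,MCF7,10.62,1.35,FALSE
15b,Caco-2,174.91,12.30,FALSE
15c,HepG2,7.57,0.66,FALSE
15c,MCF7,16.32,1.48,FALSE
15c,Caco-2,46.06,3.17,FALSE
doxorubicin,HepG2,5.43,0.24,FALSE
doxorubicin,MCF7,3.18,0.32,FALSE
doxorubicin,Caco-2,4.10,1.37,FALSE
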