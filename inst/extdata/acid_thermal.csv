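catalyst_conc,time_s,temperature_C,sludge_conc,protein_mg_L
16.56,18000,140,40.97,14724
12.88,10800,130,41.98,13380
12.88,14400,140,88.99,29174
12.88,18000,120,66.11,20574
9.2,10800,140,61.48,18211
27.6,10800,120,66.58,18123.23
9.2,10800,120,67.9,15759.72
16.56,14400,130,90.88,27235.69
5.52,10800,120,64.88,12161.12
16.56,10800,100,64.11,12112.62
16.56,14400,130,65.98,18663.38
9.2,14400,120,45.79,10189
16.56,10800,110,66.92,14466.46
16.56,10800,120,60.9,17512.62
16.56,10800,130,60.34,18189.54
16.56,18000,130,67.89,18463.38
16.56,14400,130,67.88,18792.62
16.56,10800,120,61.48,18687.44
12.88,10800,120,62.8,17275.51
9.2,18000,130,88.89,18589
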