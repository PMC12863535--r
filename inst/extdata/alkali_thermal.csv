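catalyst_conc,time_s,temperature_C,sludge_conc,protein_mg_L
1,10800,120,68.5,11987.09
2,10800,110,91.34,13999.92
2,14400,120,68.51,13077.23
2,18000,130,45.67,11001.08
1.6,10800,120,66.4,12722.53
3,14400,130,92.55,26098.77
3,10800,120,44.88,10580.31
3,10800,120,69.9,16924.63
3,10800,120,64.4,18888.14
3,10800,140,68.9,16197.61
3,7200,120,66.9,12865.68
3,18000,110,68.21,11183.38
2,10800,120,65.9,13199.72
3,10800,100,66.6,9209.544
3,10800,120,66.5,17421.47
3,10800,110,68.9,11756.91
4,14400,110,47.77,10503.38
4,10800,120,65.8,17309.19
3,14400,120,91.22,22461.47
3,14400,120,68.8,17014.46
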