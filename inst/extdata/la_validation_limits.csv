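level_mg_per_100mL,mean_mg_per_100mL,relative_bias_pct,recovery_pct,repeatability_pct,intermediate_precision_pct,l_pct,u_pct
5,6.52,30.4,130.4,3.89,8.21,-59.18,119.99
10,10.67,6.7,106.7,1.89,1.89,-14.8,28.21
20,20.43,2.15,102.15,2.07,2.07,-9.11,13.41
50,49.72,-0.56,99.44,8.34,9.46,-10.17,9.07
100,102.02,2.63,102.63,11.76,13.61,-10.24,14.96
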