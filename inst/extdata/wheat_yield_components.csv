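component,low,optimum,lsd_05,cv_pct,p
1000-GW (g),41.35,44.26,3.11,9.7,ns
SN,4.21,15.38,1.83,25,<0.001
GN,34.8,37.88,3.84,14.1,ns
Harvest index,49.41,46.36,3.02,8.4,0.05
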