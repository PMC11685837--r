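algorithm,threshold,sensitivity,specificity,precision,accuracy,f1
PoPMuSiC-2.0,-0.5,0.105,1.000,1.000,0.757,0.190
CUPSAT,-1.5,0.105,0.980,0.657,0.743,0.182
Dmutant,-1.5,0.200,0.957,0.633,0.751,0.304
Eris,-2.5,0.211,0.965,0.690,0.760,0.323
Imutant,-1,0.053,0.957,0.313,0.711,0.090
GRAPE,-1.5/-1/-2.5,0.389,0.906,0.607,0.766,0.474
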