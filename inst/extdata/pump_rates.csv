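sugar,day,pump_rate_g_per_h,D_per_h
glucose,1,4.20,0.0035
glucose,2,4.19,0.0035
glucose,3,4.19,0.0034
glucose,4,3.45,0.0027
xylose,1,5.40,0.0044
xylose,2,4.20,0.0033
xylose,3,4.19,0.0032
xylose,4,4.22,0.0032
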