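process,sugar,t_start_h,t_end_h,Qs_gLh
standard,glucose,0,24,0.57
standard,glucose,24,48,1.33
standard,glucose,48,72,1.00
standard,glucose,72,96,0.63
standard,glucose,96,120,0.58
standard,glucose,120,144,0.56
cfs,glucose,0,24,0.53
cfs,glucose,24,48,1.79
cfs,glucose,48,72,0.99
cfs,glucose,72,96,0.79
cfs,glucose,96,120,0.63
cfs,glucose,120,144,0.58
standard,xylose,0,24,0.39
standard,xylose,24,48,1.37
standard,xylose,48,72,1.06
standard,xylose,72,96,0.91
standard,xylose,96,120,0.55
standard,xylose,120,144,0.43
cfs,xylose,0,24,0.24
cfs,xylose,24,48,1.26
cfs,xylose,48,72,1.13
cfs,xylose,72,96,0.85
cfs,xylose,96,120,0.68
cfs,xylose,120,144,0.62
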