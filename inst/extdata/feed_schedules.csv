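process,sugar,component,t_h,sugar_g
standard,glucose,batch,0,60
standard,glucose,pulse,24,71.5
standard,glucose,pulse,48,46
standard,glucose,pulse,72,37.5
standard,glucose,pulse,120,54
standard,xylose,batch,0,60
standard,xylose,pulse,24,23
standard,xylose,pulse,48,46
standard,xylose,pulse,72,30
standard,xylose,pulse,96,23.5
standard,xylose,pulse,120,21.5
cfs,glucose,batch,0,71
cfs,glucose,pulse,48,31.5
cfs,glucose,pulse,72,24.5
cfs,glucose,pulse,96,21
cfs,glucose,pulse,120,21
cfs,xylose,batch,0,49
cfs,xylose,pulse,48,24.5
cfs,xylose,pulse,72,19
cfs,xylose,pulse,96,13
cfs,xylose,pulse,120,14.5
continuous,glucose,batch,0,71
continuous,glucose,fedbatch,48,89
continuous,xylose,batch,0,49
continuous,xylose,fedbatch,48,101
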