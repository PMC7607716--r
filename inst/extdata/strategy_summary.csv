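process,sugar,applied_g,metabolized_g,pct_used,final_cdw_gL,final_fame_pct,final_titer_gL,final_acid_gL,total_co2_g,co2_per_cdw
standard,glucose,269,150.66,56.01,19.38,30.82,5.98,19.78,84.62,2.98
continuous,glucose,160,145.35,90.84,26.78,28.34,7.41,10.38,109.79,3.58
standard,xylose,204,147.88,72.49,27.98,26.87,7.54,0.90,84.96,2.42
continuous,xylose,150,138.46,92.30,25.38,27.53,6.68,0.64,118.90,3.83
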