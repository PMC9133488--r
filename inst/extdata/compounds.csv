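name,mw,logp,compound_type,pka1,pka2,bp,fu,psa,hbd,papp,papp_assay,liver_clint,liver_clint_unit,liver_vmax,liver_km,liver_fu_inc,gut_clint,gut_clint_unit,gut_vmax,gut_km,gut_fu_inc
phenacetin,179.2,1.58,neutral,,,1,0.32,38.33,1,,,27,ul/min/1e6 cells,,,1,,,0.25,56.7,1
tolbutamide,270.35,2.34,monoprotic acid,5.16,,1.33,0.048,80.65,2,,,4.7,ul/min/mg,,,1,,,,,
omeprazole,345.42,2.23,ampholyte,8.8,4.2,0.66,0.19,86.7,1,,,158,ul/min/mg,,,1,,,780,6.97,1
metoprolol,267.4,2.06,monoprotic base,9.7,,1,0.86,50.7,2,,,32,ul/min/mg,,,1,10.5,ul/min/mg,,,1
chlorzoxazone,169.56,1.6,monoprotic acid,8.3,,1.22,0.27,38.3,1,,,14.9,ul/min/mg,,,1,,,,,
nifedipine,346.3,2.2,monoprotic base,2.82,,0.59,0.038,110,1,,,139,ul/min/mg,,,1,6.4,ul/min/mg,,,1
baicalein,270.24,1.7,monoprotic acid,5.4,,1.27,0.054,87,3,,,436,ul/min/mg,,,1,298,ul/min/mg,,,1
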