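compound,dose_mg_per_kg,fu_lo,fu_hi,clint_lo,clint_hi,clint_unit
phenacetin,10,0.145,0.5,20.7,78,ul/min/1e6 cells
tolbutamide,50,0.0201,0.268,2.72,8.1,ul/min/mg
omeprazole,10,0.105,0.232,119,188,ul/min/mg
metoprolol,2.5,0.80,0.925,17.1,59.9,ul/min/mg
chlorzoxazone,50,0.046,0.373,5,38.8,ul/min/mg
nifedipine,3,0.01,0.08,35.18,402,ul/min/mg
baicalein,121,0.029,0.0791,338.9,574.11,ul/min/mg
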