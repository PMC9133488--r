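compound,dose_mg_per_kg,tmax_h,cmax_ug_ml,auc_ug_h_ml
phenacetin,5,0.25,3.34,2.47
phenacetin,10,0.25,6.69,4.95
phenacetin,20,0.25,13.37,9.90
tolbutamide,50,1.38,206.74,1965.99
omeprazole,10,0.42,0.31,0.38
omeprazole,20,0.40,0.81,0.96
omeprazole,40,0.37,2.88,3.26
metoprolol,2.5,0.65,0.21,0.51
metoprolol,5,0.65,0.41,1.01
metoprolol,10,0.65,0.83,2.02
chlorzoxazone,50,0.40,68.66,124.78
nifedipine,3,0.54,2.13,3.18
nifedipine,5,0.54,3.56,5.30
nifedipine,6,0.54,4.27,6.36
baicalein,121,0.24,1.05,0.98
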