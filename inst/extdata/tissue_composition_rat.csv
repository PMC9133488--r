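# Rat tissue composition for mechanistic tissue:plasma partition prediction.
# Adapted from the published tissue-composition framework of Rodgers & Rowland
# (J Pharm Sci 2005;94:1259-76 and J Pharm Sci 2006;95:1238-57) with fractional
# organ volumes from Brown et al. (Toxicol Ind Health 1997;13:407-84).
# frac_volume: fraction of body volume (density ~1 g/ml assumed).
# f_ew / f_iw: fractional extracellular / intracellular water content.
# f_nl / f_np: fractional neutral lipid / neutral phospholipid content.
# ap_mg_g: acidic phospholipid concentration (mg/g tissue).
# albumin_ratio: tissue:plasma albumin concentration ratio.
# ph_iw: intracellular water pH.
tissue,frac_volume,f_ew,f_iw,f_nl,f_np,ap_mg_g,albumin_ratio,ph_iw
adipose,0.0761,0.135,0.017,0.853,0.0016,0.40,0.049,7.0
bone,0.0414,0.100,0.346,0.017,0.0017,0.67,0.100,7.0
brain,0.0057,0.162,0.620,0.039,0.0015,0.40,0.048,7.0
gut,0.0269,0.282,0.475,0.038,0.0125,2.41,0.158,7.0
heart,0.0033,0.320,0.456,0.014,0.0111,2.25,0.157,7.0
kidney,0.0073,0.273,0.483,0.012,0.0242,5.03,0.130,7.0
liver,0.0366,0.161,0.573,0.014,0.0240,4.56,0.086,7.0
lung,0.0050,0.336,0.446,0.022,0.0128,3.91,0.212,7.0
muscle,0.4043,0.118,0.630,0.010,0.0072,1.53,0.064,7.0
skin,0.1903,0.382,0.291,0.060,0.0044,1.32,0.277,7.0
spleen,0.0020,0.207,0.579,0.0077,0.0113,3.18,0.097,7.0
plasma,0.0312,0.960,0.000,0.0023,0.0013,0.00,1.000,7.4
erythrocyte,0.0266,0.000,0.603,0.0017,0.0029,0.50,0.000,7.22
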