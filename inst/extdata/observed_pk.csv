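compound,dose_mg_per_kg,obs_id,tmax_h,tmax_sd,cmax_ug_ml,cmax_sd,auc_ug_h_ml,auc_sd,reference
phenacetin,5,1,0.33-0.50,,1.73,,1.52,,B97
phenacetin,10,1,0.50,,6.28,1.94,9.79,3.58,B48
phenacetin,10,2,,,3.94,0.81,4.69,0.86,B75
phenacetin,20,1,0.25,,9.00,,13.12,,B89
tolbutamide,50,1,0.91,0.37,232.00,35.00,1309.00,40.00,B57
tolbutamide,50,2,1.42,0.56,176.00,37.20,1228.00,153.00,B58
omeprazole,10,1,0.36,0.22,0.44,0.12,0.59,0.14,B32
omeprazole,10,2,0.10,0.10,0.33,0.01,0.47,0.13,B48
omeprazole,10,3,0.21,0.02,0.50,0.12,0.29,0.07,B35
omeprazole,10,4,,,1.13,0.18,1.13,0.16,B75
omeprazole,20,1,0.25,0.02,1.43,0.38,0.86,0.15,B35
omeprazole,20,2,0.25,0.00,1.01,0.17,0.73,0.06,B88
omeprazole,20,3,0.50,0.00,2.01,0.14,1.50,0.08,B73
omeprazole,40,1,0.29,0.22,2.11,0.99,1.57,0.54,B40
omeprazole,40,2,0.17,0.09,2.61,0.55,2.10,0.93,B94
omeprazole,40,3,0.68,0.82,2.66,2.00,3.08,1.44,B42
omeprazole,40,4,0.35,0.39,3.30,1.65,2.27,1.07,B43
omeprazole,40,5,0.27,0.02,2.44,0.63,2.26,0.52,B35
omeprazole,40,6,0.10,0.06,4.89,1.33,1.98,0.60,B39
omeprazole,40,7,0.35,0.32,2.43,1.17,1.92,0.88,B41
metoprolol,2.5,1,0.50,0.00,0.16,0.00,0.21,0.02,B55
metoprolol,2.5,2,0.47,0.07,0.16,0.01,0.22,0.02,B54
metoprolol,5,1,0.50,,0.40,,0.45,,B37
metoprolol,10,1,0.60,0.30,0.57,0.25,1.66,0.58,B48
metoprolol,10,2,0.70,0.50,0.81,0.28,1.35,0.59,B86
metoprolol,10,3,,,0.53,0.066,1.49,0.39,B75
chlorzoxazone,50,1,0.25,,23.10,8.59,41.67,8.48,B1
chlorzoxazone,50,2,0.14,0.08,31.80,13.10,46.83,16.00,B3
chlorzoxazone,50,3,0.10,0.06,30.50,8.17,39.83,4.08,B3
nifedipine,3,1,0.25,,2.00,0.68,2.23,0.42,B13
nifedipine,3,2,0.47,0.03,2.46,0.29,4.30,0.45,B24
nifedipine,3,3,0.25,,1.48,0.38,2.84,0.19,B36
nifedipine,3,4,0.58,0.13,1.68,0.58,3.38,0.60,B87
nifedipine,5,1,0.38,0.06,1.76,0.20,2.72,0.34,B53
nifedipine,5,2,0.12-0.50,,1.95,0.26,2.73,0.40,B28
nifedipine,5,3,0.12-1.50,,1.96,0.23,3.75,0.63,B28
nifedipine,5,4,0.12-1.00,,2.56,0.23,4.38,0.29,B28
nifedipine,6,1,0.20-0.57,,5.23,,5.75,,B20
nifedipine,6,2,0.16-0.40,,5.88,,5.90,,B19
baicalein,121,1,0.17,0.00,1.24,0.78,0.79,0.08,B95
baicalein,121,2,0.17,0.00,1.67,0.85,0.79,0.08,B26
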