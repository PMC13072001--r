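diet_id,bw_kg,dm_intake_kg_d,dig_dm,dig_om,dig_ge,dig_cp,dig_ndf,dig_adf,dig_ee,ue_pct_de,ch4_pct_de,me_de_pct,ne_me_pct,n_intake_g_d,n_feces_g_d,n_urine_g_d,n_retention_g_d
basal,215.78,2.11,88.33,91.02,87.95,84.77,52.46,55.90,70.33,7.12,0.93,91.95,84.79,48.28,7.58,2.53,28.05
BL-1,235.13,2.21,85.56,88.50,85.66,83.48,51.75,40.27,75.46,6.90,0.70,92.40,83.36,49.87,8.52,2.84,27.73
BL-2,235.13,2.30,83.92,86.79,83.19,81.76,52.01,25.19,71.77,5.53,0.98,93.49,84.23,51.71,9.76,3.25,23.91
BL-3,226.83,2.22,84.52,87.60,84.44,82.62,44.22,27.65,65.01,4.97,0.98,94.05,84.80,52.44,9.49,3.16,26.81
BL-4,227.07,2.08,84.12,87.05,84.78,82.55,43.32,25.29,72.73,6.56,0.96,92.48,82.72,47.32,8.50,2.83,26.09
BL-5,221.80,2.13,84.38,87.31,84.21,82.27,49.04,38.21,53.64,8.14,0.78,91.08,83.23,47.16,8.69,2.90,24.34
BL-6,188.13,1.86,83.28,86.11,82.52,77.55,43.07,27.60,44.16,6.78,0.98,92.24,83.91,42.81,9.93,3.31,28.23
BL-7,194.30,1.90,84.31,87.25,83.93,80.52,38.88,21.82,41.51,6.61,0.96,92.42,89.92,45.11,9.12,3.04,28.47
BL-8,192.17,1.91,83.64,86.46,83.19,79.15,43.86,25.88,52.54,7.74,0.89,91.37,88.82,43.79,9.44,3.15,26.73
BL-9,202.20,1.99,83.97,86.84,83.55,79.45,42.54,29.30,46.10,4.96,1.04,93.99,89.63,45.47,9.63,3.21,26.72
BL-10,199.53,1.98,85.45,88.20,84.88,81.24,52.07,40.15,39.60,5.56,0.73,93.71,91.26,44.32,8.52,2.84,26.32
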