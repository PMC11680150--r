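# Observed diet-level results (least-squares means over 6 replicates per
# diet): DE and ME (MJ/kg) on both bases, the ME/DE ratio (%), and apparent
# total tract digestibility (%). Known misprint preserved as published:
# the corn 1 diet as-fed ME (14.72) exceeds its as-fed DE.
response,basis,corn 1 diet,corn 2 diet,corn 3 diet,corn 4 diet,corn 5 diet,wheat 1 diet,wheat 2 diet,rice 1 diet,rice 2 diet,rice 3 diet,rice 4 diet,rice 5 diet,rice 6 diet,sem,p_value
de_mj_per_kg,as_fed,14.45,14.08,13.32,13.62,13.76,13.44,13.71,14.19,12.35,13.55,14.37,13.07,12.94,0.07,0.01
me_mj_per_kg,as_fed,14.72,13.75,12.99,13.26,13.47,13.09,13.25,13.87,12.23,13.14,14.08,12.81,12.66,0.08,0.01
de_mj_per_kg,dry_matter,16.18,15.96,15.31,15.55,15.88,15.25,15.42,16.16,13.96,14.89,16.23,14.87,14.75,0.08,0.01
me_mj_per_kg,dry_matter,15.87,15.59,14.93,15.14,15.54,14.85,14.90,15.80,13.82,14.44,15.90,14.57,14.53,0.08,0.01
me_de_ratio_pct,dry_matter,98.09,97.66,97.50,97.36,97.87,97.40,96.59,97.75,99.01,96.96,97.98,98.00,97.80,0.11,0.01
attd_GE,dry_matter,87.77,90.27,86.07,86.96,87.72,87.58,87.17,93.28,81.96,72.50,90.75,84.57,83.83,0.58,0.01
attd_DM,dry_matter,88.43,91.16,87.52,87.90,88.58,88.54,87.47,93.83,81.77,67.38,90.32,83.86,83.47,0.73,0.01
attd_ash,dry_matter,45.83,50.12,53.86,46.04,41.99,48.39,36.87,57.33,35.24,22.50,30.52,27.35,22.51,1.55,0.01
attd_NDF,dry_matter,55.09,54.12,50.96,56.32,54.82,64.21,56.78,58.91,25.61,17.79,63.27,28.10,31.24,1.86,0.01
attd_ADF,dry_matter,50.39,47.27,9.31,49.78,57.60,40.74,25.80,40.70,15.60,7.31,13.01,11.97,17.35,2.22,0.01
attd_CP,dry_matter,76.36,83.01,73.89,77.70,78.48,87.58,83.63,86.81,77.19,66.23,80.33,78.32,78.38,0.71,0.01
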