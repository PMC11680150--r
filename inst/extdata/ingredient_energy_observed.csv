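# Observed ingredient-level results: DE and ME (MJ/kg) on both bases,
# ME/DE ratio (%), and apparent total tract digestibility (%). Rice 5 and
# rice 6 were evaluated by the difference method against corn 5, the rest
# by the direct method.
response,basis,corn 1,corn 2,corn 3,corn 4,corn 5,wheat 1,wheat 2,rice 1,rice 2,rice 3,rice 4,rice 5,rice 6,sem,p_value
de_mj_per_kg,as_fed,14.84,14.45,13.68,13.98,14.13,13.79,14.08,14.57,12.68,13.91,14.75,13.42,13.29,0.13,0.01
me_mj_per_kg,as_fed,14.55,14.12,13.34,13.61,13.83,13.43,13.60,14.24,12.56,13.49,14.46,13.15,13.00,0.15,0.01
de_mj_per_kg,dry_matter,17.05,16.40,15.88,16.09,16.75,15.45,16.00,16.78,14.49,15.49,16.63,14.18,13.77,0.16,0.01
me_mj_per_kg,dry_matter,16.73,16.02,15.48,15.67,16.40,15.05,15.46,16.40,14.35,15.02,16.30,13.87,13.40,0.17,0.01
me_de_ratio_pct,dry_matter,98.10,97.66,97.50,97.37,97.88,97.39,96.59,97.75,99.01,96.96,97.98,97.84,97.30,0.21,0.01
attd_GE,dry_matter,87.77,90.27,86.07,86.96,87.72,87.58,87.17,93.28,81.96,72.50,90.75,69.10,63.15,0.83,0.01
attd_DM,dry_matter,88.43,91.15,87.52,87.90,88.58,88.54,87.47,93.84,81.77,67.38,90.32,74.67,66.08,0.99,0.01
attd_ash,dry_matter,45.83,50.12,53.86,46.04,41.99,48.39,36.87,57.33,35.24,22.50,30.52,10.66,16.38,2.23,0.01
attd_NDF,dry_matter,55.09,54.12,50.96,56.32,54.82,64.21,56.78,58.91,25.61,17.79,63.27,57.48,40.69,2.28,0.01
attd_ADF,dry_matter,50.39,47.27,9.31,49.78,57.60,40.74,25.80,40.70,15.60,7.31,13.01,35.99,39.44,2.53,0.01
attd_CP,dry_matter,76.36,83.01,73.89,77.70,78.48,87.58,83.63,86.81,77.19,66.23,80.32,86.40,80.77,1.01,0.01
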