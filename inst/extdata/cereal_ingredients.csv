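# Proximate composition and gross energy of the 13-cereal panel
# (5 corn, 2 wheat, 6 rice), dry-matter basis; dm_pct is % of fresh weight.
name,basis,dm_pct,ash_pct,ee_pct,ndf_pct,adf_pct,cp_pct,starch_pct,ge_mj_per_kg
corn 1,dry_matter,87.01,1.36,3.62,12.94,3.42,8.11,65.85,18.43
corn 2,dry_matter,88.11,1.37,4.35,11.62,2.80,8.89,66.54,18.50
corn 3,dry_matter,86.16,1.65,2.74,13.33,3.25,9.30,64.78,18.22
corn 4,dry_matter,86.91,1.79,3.01,11.55,2.31,8.98,67.77,18.37
corn 5,dry_matter,86.58,1.18,2.97,7.18,1.60,12.63,68.34,18.58
wheat 1,dry_matter,89.28,1.93,1.34,14.84,3.50,16.25,57.52,18.41
wheat 2,dry_matter,87.95,1.73,1.30,19.51,3.62,16.14,53.43,18.28
rice 1,dry_matter,86.86,1.46,2.75,6.74,1.78,9.35,71.45,18.32
rice 2,dry_matter,87.49,4.44,1.59,16.01,10.78,8.27,61.76,17.92
rice 3,dry_matter,89.80,4.20,16.12,18.19,7.61,16.13,37.53,21.20
rice 4,dry_matter,88.70,1.94,3.58,18.04,3.95,9.31,59.22,18.31
rice 5,dry_matter,88.85,5.40,2.02,22.23,14.76,7.88,54.48,17.84
rice 6,dry_matter,89.09,5.55,1.74,27.65,14.80,7.88,49.45,17.72
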