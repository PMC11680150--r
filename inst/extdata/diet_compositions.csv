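# Analysed proximate composition and gross energy of the 13 experimental
# diets, dry-matter basis; dm_pct is % of fresh weight.
name,basis,dm_pct,ash_pct,ee_pct,ndf_pct,adf_pct,cp_pct,starch_pct,ge_mj_per_kg
corn 1 diet,dry_matter,89.33,3.77,3.82,12.91,3.49,8.21,64.24,18.55
corn 2 diet,dry_matter,88.22,3.46,2.40,8.80,2.45,8.86,69.25,17.68
corn 3 diet,dry_matter,87.00,3.99,0.82,12.72,2.03,9.14,66.57,17.79
corn 4 diet,dry_matter,87.57,4.12,2.85,12.20,3.08,9.27,64.27,17.88
corn 5 diet,dry_matter,86.66,3.45,3.01,9.85,2.76,9.66,67.32,18.10
wheat 1 diet,dry_matter,88.10,3.99,0.87,15.83,4.07,15.24,57.34,17.41
wheat 2 diet,dry_matter,88.88,4.04,1.09,14.79,3.91,15.31,57.85,17.70
rice 1 diet,dry_matter,87.82,3.58,1.29,5.91,1.89,9.15,73.42,17.32
rice 2 diet,dry_matter,88.49,5.88,0.98,16.52,10.67,7.63,61.58,17.03
rice 3 diet,dry_matter,90.98,10.10,15.47,17.91,8.00,15.30,34.43,20.54
rice 4 diet,dry_matter,88.56,3.98,2.74,13.24,3.80,8.26,64.67,17.88
rice 5 diet,dry_matter,87.88,5.11,2.54,13.91,7.11,9.37,62.43,17.58
rice 6 diet,dry_matter,87.15,4.33,2.13,15.31,7.95,8.96,62.75,17.71
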