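# Diet recipes, as-fed inclusion %. Eleven single-cereal diets carry 97.4%
# of their cereal; the rice 5 and rice 6 test diets replace 40% of the
# basal cereal (58.44 + 38.96 = 97.4). The printed recipe table lists the
# 58.44% basal under its first corn row, but the accompanying footnote and
# the design description state the basal cereal of the rice 5/6 diets is
# corn 5; the footnote is followed here.
diet_name,ingredient,inclusion_pct,energy_bearing
corn 1 diet,corn 1,97.4,1
corn 1 diet,dicalcium phosphate,0.9,0
corn 1 diet,limestone,0.9,0
corn 1 diet,NaCl,0.3,0
corn 1 diet,premix,0.5,0
corn 2 diet,corn 2,97.4,1
corn 2 diet,dicalcium phosphate,0.9,0
corn 2 diet,limestone,0.9,0
corn 2 diet,NaCl,0.3,0
corn 2 diet,premix,0.5,0
corn 3 diet,corn 3,97.4,1
corn 3 diet,dicalcium phosphate,0.9,0
corn 3 diet,limestone,0.9,0
corn 3 diet,NaCl,0.3,0
corn 3 diet,premix,0.5,0
corn 4 diet,corn 4,97.4,1
corn 4 diet,dicalcium phosphate,0.9,0
corn 4 diet,limestone,0.9,0
corn 4 diet,NaCl,0.3,0
corn 4 diet,premix,0.5,0
corn 5 diet,corn 5,97.4,1
corn 5 diet,dicalcium phosphate,0.9,0
corn 5 diet,limestone,0.9,0
corn 5 diet,NaCl,0.3,0
corn 5 diet,premix,0.5,0
wheat 1 diet,wheat 1,97.4,1
wheat 1 diet,dicalcium phosphate,0.9,0
wheat 1 diet,limestone,0.9,0
wheat 1 diet,NaCl,0.3,0
wheat 1 diet,premix,0.5,0
wheat 2 diet,wheat 2,97.4,1
wheat 2 diet,dicalcium phosphate,0.9,0
wheat 2 diet,limestone,0.9,0
wheat 2 diet,NaCl,0.3,0
wheat 2 diet,premix,0.5,0
rice 1 diet,rice 1,97.4,1
rice 1 diet,dicalcium phosphate,0.9,0
rice 1 diet,limestone,0.9,0
rice 1 diet,NaCl,0.3,0
rice 1 diet,premix,0.5,0
rice 2 diet,rice 2,97.4,1
rice 2 diet,dicalcium phosphate,0.9,0
rice 2 diet,limestone,0.9,0
rice 2 diet,NaCl,0.3,0
rice 2 diet,premix,0.5,0
rice 3 diet,rice 3,97.4,1
rice 3 diet,dicalcium phosphate,0.9,0
rice 3 diet,limestone,0.9,0
rice 3 diet,NaCl,0.3,0
rice 3 diet,premix,0.5,0
rice 4 diet,rice 4,97.4,1
rice 4 diet,dicalcium phosphate,0.9,0
rice 4 diet,limestone,0.9,0
rice 4 diet,NaCl,0.3,0
rice 4 diet,premix,0.5,0
rice 5 diet,corn 5,58.44,1
rice 5 diet,rice 5,38.96,1
rice 5 diet,dicalcium phosphate,0.9,0
rice 5 diet,limestone,0.9,0
rice 5 diet,NaCl,0.3,0
rice 5 diet,premix,0.5,0
rice 6 diet,corn 5,58.44,1
rice 6 diet,rice 6,38.96,1
rice 6 diet,dicalcium phosphate,0.9,0
rice 6 diet,limestone,0.9,0
rice 6 diet,NaCl,0.3,0
rice 6 diet,premix,0.5,0
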