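# Published DE/ME prediction equations for mixed cereal panels (as-fed
# basis). p values are upper bounds (< 0.01 as published). These shipped
# coefficients are reference values for application; they are not
# recomputable from the shipped panel means (see the methods vignette).

response: DE
basis: as_fed
intercept: 14.3722
coef.ADF: -0.1740
r2: 0.7899
p: 0.01

response: DE
basis: as_fed
intercept: 11.4467
coef.starch: 0.1364
coef.ADF: -0.2352
r2: 0.8633
p: 0.01

response: ME
basis: as_fed
intercept: 0.0636
coef.DE: 0.9716
r2: 0.9907
p: 0.01

response: ME
basis: as_fed
intercept: 0.0538
coef.DE: 0.9838
coef.CP: -0.0165
r2: 0.9943
p: 0.01
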