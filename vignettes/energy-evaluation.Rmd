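---
title: "Determining and predicting available energy in swine feed ingredients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining and predicting available energy in swine feed ingredients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedenergy)
```

## The measurement model

A total-collection digestion trial feeds each pig a known diet and
quantitatively collects feces and urine over a fixed window (here 5 d,
after 7 d of adaptation). With `GE_i`, `GE_f`, `GE_u` the gross energies
(MJ) of intake, feces and urine and `FI` the dry-matter feed intake (kg)
over the window, the diet-level quantities are

* digestible energy `DE = (GE_i − GE_f) / FI`,
* metabolizable energy `ME = (GE_i − GE_f − GE_u) / FI` (gaseous losses
  ignored, as is conventional for growing pigs),
* apparent total tract digestibility of a nutrient
  `ATTD = (N_d·FI − N_f·FO) / (N_d·FI)`, with `N_d`, `N_f` the nutrient
  concentrations (% DM) of diet and feces and `FO` the fecal DM output.

These hold per pig × period record; everything downstream is algebra on
them plus design-aware averaging.

**Diet level carries no inclusion correction.** Trial reports sometimes
write the balance formula with the energy-bearing inclusion (0.974)
already divided in while still labelling the result a *diet* value. We
deliberately keep the two steps separate: the record-level formulas above
give diet values, and the inclusion divides only in
`ingredient_energy_direct()`. This is the only reading under which the
shipped diet-level and ingredient-level observed tables are mutually
consistent (as-fed ingredient cell = as-fed diet cell / 0.974 at the
printed precision for every reconciling pair), and it keeps each function
meaningful on its own.

**Units.** Energies are MJ throughout. Balance tables recorded in kcal are
converted at ingest (1 kcal = 4.184 kJ) with a logged message, because
balance formulas are traditionally stated in kcal while results are
reported in MJ. Percentages are stored on the 0–100 scale exactly as
printed in feed tables, never as fractions.

**Bases.** Every composition profile and energy result carries an explicit
`as_fed` or `dry_matter` basis, and all cross-table operations fail loudly
on a mismatch instead of converting silently. Mixed bases are the main
ambiguity in feed-table work: composition panels are typically reported on
DM basis while prediction equations are often applied as-fed. Conversion
multiplies (to as-fed) or divides (to DM) analytes and GE by the
dry-matter fraction and is exactly invertible; the round trip is tested to
1e−9 relative.

## Ingredient evaluation

*Direct method.* When the test cereal is the diet's sole energy source
(97.4 % inclusion with a nutrient-free mineral/vitamin remainder), the
ingredient value is the diet value divided by the inclusion fraction.

*Difference method.* Fibrous ingredients that cannot be fed as a sole
source are evaluated by replacing a fraction of a basal cereal. Two modes
are implemented, and the caller must pick one — the package sets no silent
default, though the pipeline front end defaults to `contribution` and logs
it:

* `contribution` — the exact inverse of the additive mixture model: the
  test diet's per-kg energy is the inclusion-weighted sum of ingredient
  contributions, so `DE_test = (DE_testdiet − f_b·DE_basal_ingredient) /
  f_t` with the as-fed mass fractions (0.5844 / 0.3896 for a 40 %
  replacement at 97.4 % total inclusion). This is the mode the simulator
  inverts exactly, and the one we recommend.
* `as_printed` — the textbook substitution formula applied to
  inclusion-corrected diet values,
  `DE_test = (DE_testdiet/0.974 − (DE_basaldiet/0.974)·(1 − R)) / 0.3896`
  with `R` the replacement fraction. It references the basal *diet* rather
  than the basal ingredient.

Both modes are provided because published replacement-diet results in this
area cannot generally be reproduced from printed diet means under either
reading, so fixing one would assert more than the data support. Per-record
difference estimates use the basal ingredient's least-squares mean as the
reference, since substitution formulas are stated with a single basal
value rather than a per-pig pairing.

*Ingredient ATTD.* The contribution logic extends to digestibility: with
`X` the test ingredient's share of the test diet's nutrient amount and `B`
the basal ingredient's share, `ATTD_test = (ATTD_testdiet −
B·ATTD_basal)/X`. For the direct method this reduces to
`ATTD_ingredient = ATTD_diet / share`. With nutrient-free mineral fillers
the share is exactly 1 for organic nutrients and gross energy — ingredient
ATTD then *equals* diet ATTD, matching how trial reports tabulate it — but
dry matter uses the ingredient's DM share, because the fillers contribute
indigestible mass. We apply the share correction uniformly rather than
copying the diet value, so that simulator round trips are exact for every
nutrient including DM; on real direct diets the correction touches only
the DM row (by the filler's ~2.6 % share).

Estimates outside \[0, 100\] % are possible with noisy difference-method
inputs; they are flagged (`flag_out_of_range`) and returned, never
clipped. Likewise ME > DE is physically impossible but can occur in noisy
records: `validate_balance()` flags violations (including fecal + urinary
energy exceeding intake) and nothing is dropped unless the caller asks.

## Aggregation

Trials of this shape assign each of `t` diets to `t` pigs over `p < t`
periods — a Youden rectangle: every diet once per period, at most once per
pig, equal replication. `diet_lsmeans()` fits `response ~ diet + period`
by ordinary least squares and reports diet least-squares means via
`emmeans`, their SE (averaged into the single SEM conventionally
tabulated), and the overall diet F-test.

Period is modelled as a **fixed** factor although trial protocols often
declare it random: with a single observation per pig-period and a balanced
row–column arrangement, the diet least-squares means coincide under both
treatments, and REML variance components would add machinery without any
testable consequence at this design size. Pairwise multiple-comparison
letterings are out of scope; significance annotation follows the usual
convention (significant below p = 0.05, tendency up to 0.10). A univariate
z-score screen (`outlier_screen()`) reports — but never removes — extreme
records.

## Correlation screening and prediction equations

`pearson_matrix()` computes pairwise Pearson correlations over the
ingredient panel with two-sided p-values from the t transform on n − 2 df.
`stepwise_fit()` builds DE/ME prediction equations by forward selection
with replacement: the candidate with the smallest partial-F p-value enters
while p ≤ `sle`; after each entry any included predictor with p > `sls` is
removed; the procedure stops at a fixed point and emits the fitted
equation at every size reached, so the model-choice criterion (largest R²
among the emitted path) stays visible. Defaults `sle = sls = 0.15` are the
classical stepwise defaults of the statistical packages this workflow
descends from; the trial literature rarely states its thresholds. Ties on
the entry p-value break lexicographically by predictor name —
deterministic and documented. Candidates collinear with the current model
are skipped with a warning. Default candidates are DM, ash, EE, NDF, ADF,
CP, starch and GE for DE, plus DE itself for ME, mirroring the variable
set of the correlation screen.

### What is — and is not — recomputable from the shipped tables

The package ships a published study's panel (13 cereals), diet recipes,
observed result tables and four published prediction equations. From the
printed values one can recompute exactly:

* the panel CV column for DM, CP, NDF, ADF, EE and ash (sample SD, n − 1 —
  this convention reproduces the printed CP CV of 31.23 to the last
  digit);
* the direct-method as-fed ingredient cells from the as-fed diet cells for
  nine of eleven direct diets (the other two differ in the final rounded
  digit), and the full as-fed → DM basis chain;
* the near-collinearity of DE and ME across ingredients (r > 0.99).

Not recomputable, and therefore shipped as reference values only, never
asserted: the printed starch CV (recomputes to ≈15.7 versus a printed
9.37), the printed DE–starch correlation of 0.84 (recomputes to ≈0.56 on
DM means, ≈0.35 as-fed), and the four published equation coefficients
(refitting on the printed means on either basis gives materially different
coefficients — the published as-fed regression line does not even pass
through the printed as-fed mean point, so per-observation data that were
never deposited must have been used). The test suite *asserts these
discrepancies* as documentation, so nobody can mistake the shipped
registry for a refit. A handful of printed DM-basis cells for the
replacement-evaluated ingredients are likewise inconsistent with their
as-fed counterparts and are not targeted.

## The synthetic-trial generator

`simulate_trial()` runs the balance formulas in reverse. Its default
conditions mirror the packaged study: 13 diets over 6 periods (cyclic
Youden construction `diet(pig, period) = (pig + period) mod t`), 45.32 kg
pigs fed 4 % of body weight daily over a 5-day collection window, true
ingredient DE/ME/ATTD from the packaged observed tables
(`example_true_params()`), and diets mixed exactly as formulated. Ether
extract digestibility is not reported at ingredient level in the packaged
tables; the preset uses 0.70, a mid-range value for cereal fat in growing
pigs.

True diet values are inclusion-weighted as-fed mixtures (fillers:
nutrient-free, indigestible, ~100 % DM); records are then generated as
`GE_f = (GE_i − FI·DE_true)(1 + ε_f)`, `GE_u = FI·(DE − ME)(1 + ε_u)`,
`FO = FI(1 − ATTD_DM)(1 + ε_f′)`, with fecal nutrient concentrations
consistent with the true ATTD up to assay noise. All noises are
multiplicative, mean-zero Gaussian, clamped at ±3 CV (clamping rather than
rejection keeps the draw count — and hence reproducibility — independent
of the realized values). Records are generated from per-pig substreams
derived deterministically from one global seed, so equal seeds give
byte-identical tables. Fecal energy is capped at `GE_i − GE_u` so the
energy-balance invariant holds by construction (with realistic CVs the cap
never binds).

Default noise CVs (fecal energy and output 10 %, urinary energy 15 %,
intake 2 %, fecal assays 3 %) are a calibration choice, not a measured
claim: per-pig variances are rarely published, and these values make a
simulated 13 × 6 trial's diet-mean SEM land near 0.08 MJ/kg for DE — the
order observed in real trials of this design. The generator emulates
measurement and animal-to-animal noise around fixed truths; it does *not*
emulate growth across periods, refusals, pig-specific digestive
efficiency, or period × diet interaction, so passing recovery tests show
the algebra chain is correct and unbiased under the stated noise model —
not that any particular real trial met those assumptions.

At zero noise the full pipeline (simulate → evaluate → aggregate) returns
every true diet and ingredient DE, ME and ATTD to 1e−9 relative; this
round trip, an unbiasedness check for the difference method (500
replicates at 2 % fecal CV, mean bias below 0.5 % of truth), and an
exhaustive-best-subset oracle for the stepwise path are part of the test
suite. Test problem sizes — 200 design-recovery seeds, 500 recovery
replicates, 100 (40 in the combined acceptance check) stepwise-oracle
instances at n ≤ 40 with 6 candidates — were chosen to keep the full suite
under a couple of minutes while leaving binomial noise in the asserted
rates well below the margins tested.

## Numerical and interface choices

* Report rounding is half-up to 2 decimals (`round_half_up()`), matching
  how trial tables are printed; machine-readable outputs are never
  rounded.
* The coverage property for least-squares means is asserted at 93 %
  rather than the nominal ~95 % of a 2·SE interval (t, 60 df): the
  nominal rate itself is just below 95 %, and 2600 pooled draws fluctuate
  by ±0.4 %; 93 % is three binomial SDs below nominal, so the test fails
  on real defects, not on sampling luck.
* `cv_summary()` refuses n < 2 and zero means rather than returning NaN.
* The pipeline auto-detects replacement diets (two energy-bearing
  cereals) and derives the replacement geometry from the recipe, warning
  if no sole-source basal diet exists.
* One recipe-table conflict is resolved in the shipped data: the printed
  recipe grid lists the replacement diets' 58.44 % basal cereal in its
  first corn row, while the table footnote and the design description name
  corn 5 as the basal; the footnote is followed, with a comment in the
  CSV.
* The command-line front end is a thin wrapper (`inst/cli/feedenergy.R`)
  over the same exported functions; `run` executes the whole pipeline, and
  its outputs re-parse under the package's own readers byte-identically
  across reruns.

## Limitations

Marker-based and ileal digestibility, net-energy systems, amino-acid
balance, least-cost formulation and REML variance components are out of
scope. The shipped prediction equations come from a single 13-ingredient
panel; applying them far outside cereal composition ranges (e.g. the
high-fat outlier in the panel shows EE up to 16 % DM) extrapolates, and
the spread between the one- and two-predictor DE equations is a useful
honesty check on such use.
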