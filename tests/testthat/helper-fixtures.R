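# Shared builders for small in-code fixtures.

# a valid random DM-basis profile; analyte ranges keep the DM-basis
# closure (starch + CP + EE + ash <= 100) satisfied by construction
random_profile <- function(name = "x") {
  nutrient_profile(
    name, "dry_matter",
    dm_pct = runif(1, 80, 95),
    ash_pct = runif(1, 1, 5), ee_pct = runif(1, 1, 5),
    ndf_pct = runif(1, 5, 25), adf_pct = runif(1, 1, 12),
    cp_pct = runif(1, 5, 15), starch_pct = runif(1, 30, 60),
    ge_mj_per_kg = runif(1, 17, 21))
}

# one balance record as a data.frame row
make_record <- function(pig_id = 1, period = 1, diet_name = "d",
                        fi = 5, fo = 0.6, ge_i = 90, ge_f = 9, ge_u = 1.8,
                        ...) {
  extra <- list(...)
  rec <- data.frame(pig_id = pig_id, period = period, diet_name = diet_name,
                    feed_intake_kg_dm = fi, feces_output_kg_dm = fo,
                    ge_intake_mj = ge_i, ge_feces_mj = ge_f,
                    ge_urine_mj = ge_u, stringsAsFactors = FALSE)
  for (nm in names(extra)) rec[[nm]] <- extra[[nm]]
  rec
}

# full packaged-study simulation under a given noise model
simulate_study <- function(noise) {
  forms <- example_formulations()
  simulate_trial(example_true_params(), forms,
                 youden_design(13, 6, diet_names = names(forms)),
                 noise = noise)
}

# evaluate the packaged study in contribution mode, muffling the
# perfect-fit warnings that zero-noise inputs provoke in lm/anova
evaluate_study <- function(records, mode = "contribution") {
  suppressWarnings(
    evaluate_trial(records, cereal_panel(), example_formulations(),
                   designs = example_difference_designs(), mode = mode))
}

summary_row <- function(summary, response, basis, names) {
  unlist(summary[summary$response == response & summary$basis == basis,
                 names, drop = FALSE])
}
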