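# Packaged study data: the 13-cereal panel, its diet recipes, the observed
# result tables, and a matching true-parameter preset for simulation.

extdata <- function(file) {
  system.file("extdata", file, package = "feedenergy", mustWork = TRUE)
}

#' Packaged 13-cereal composition panel
#'
#' Proximate composition and gross energy of the study panel (5 corn,
#' 2 wheat, 6 rice), dry-matter basis.
#'
#' @return ingredient panel data.frame (see [read_ingredient_table()]).
#' @export
cereal_panel <- function() {
  read_ingredient_table(extdata("cereal_ingredients.csv"))
}

#' Packaged diet formulations
#'
#' The 13 experimental diets: eleven single-cereal diets at 97.4% cereal
#' inclusion and two 40%-replacement test diets (rice 5, rice 6 against a
#' corn 5 basal).
#'
#' @return named list of [formulation_spec()]s.
#' @export
example_formulations <- function() {
  read_diet_table(extdata("diet_formulations.csv"))
}

#' Packaged analysed diet compositions
#'
#' @return panel-layout data.frame of the 13 diets (dry-matter basis).
#' @export
reference_diet_compositions <- function() {
  read_ingredient_table(extdata("diet_compositions.csv"))
}

read_observed <- function(file) {
  utils::read.csv(extdata(file), comment.char = "#",
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' Observed diet- and ingredient-level result tables
#'
#' Published least-squares means in the wide report shape: one row per
#' response, one column per diet (or ingredient), plus `sem` and `p_value`.
#'
#' @return data.frame.
#' @export
reference_diet_results <- function() read_observed("diet_energy_observed.csv")

#' @rdname reference_diet_results
#' @export
reference_ingredient_results <- function() {
  read_observed("ingredient_energy_observed.csv")
}

#' Look up one cell of an observed result table
#'
#' @param table output of [reference_diet_results()] or
#'   [reference_ingredient_results()].
#' @param response response row name (e.g. `"de_mj_per_kg"`).
#' @param basis `"as_fed"` or `"dry_matter"`.
#' @param name diet or ingredient column name.
#' @return numeric scalar.
#' @export
reference_value <- function(table, response, basis, name) {
  row <- table$response == response & table$basis == basis
  if (sum(row) != 1L || !name %in% names(table)) {
    fe_stop(sprintf("no unique cell for (%s, %s, %s)", response, basis, name),
            "feedenergy_invalid_input")
  }
  table[[name]][row]
}

#' True-parameter preset mirroring the packaged study
#'
#' Builds [true_ingredient_params()] for all 13 cereals from the packaged
#' composition panel and the observed dry-matter-basis ingredient results:
#' DE/ME from the energy rows and ATTD fractions from the digestibility
#' rows. Ether-extract digestibility is not reported at ingredient level
#' and defaults to 0.70, a mid-range value for cereal fat in growing pigs.
#'
#' @param ee_attd ether-extract ATTD fraction applied to every ingredient.
#' @return named list of [true_ingredient_params()].
#' @export
example_true_params <- function(ee_attd = 0.70) {
  panel <- cereal_panel()
  obs <- reference_ingredient_results()
  params <- lapply(panel$name, function(nm) {
    true_ingredient_params(
      profile = panel_profile(panel, nm),
      true_de_mj_per_kg_dm = reference_value(obs, "de_mj_per_kg",
                                             "dry_matter", nm),
      true_me_mj_per_kg_dm = reference_value(obs, "me_mj_per_kg",
                                             "dry_matter", nm),
      true_attd = c(
        DM = reference_value(obs, "attd_DM", "dry_matter", nm) / 100,
        CP = reference_value(obs, "attd_CP", "dry_matter", nm) / 100,
        NDF = reference_value(obs, "attd_NDF", "dry_matter", nm) / 100,
        ADF = reference_value(obs, "attd_ADF", "dry_matter", nm) / 100,
        ash = reference_value(obs, "attd_ash", "dry_matter", nm) / 100,
        EE = ee_attd))
  })
  setNames(params, panel$name)
}

#' Difference designs of the packaged study
#'
#' The two 40%-replacement evaluations: rice 5 and rice 6 against the
#' corn 5 basal at a 97.4% total energy-bearing inclusion (fractions
#' 0.5844 / 0.3896).
#'
#' @return named list of [difference_design()]s keyed by test ingredient.
#' @export
example_difference_designs <- function() {
  list(
    "rice 5" = difference_design("rice 5", "corn 5", "corn 5 diet",
                                 "rice 5 diet"),
    "rice 6" = difference_design("rice 6", "corn 5", "corn 5 diet",
                                 "rice 6 diet"))
}
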