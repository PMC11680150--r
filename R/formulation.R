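# Diet recipes and the replacement geometry behind the direct and
# difference methods of ingredient evaluation.

#' Create a diet formulation
#'
#' A formulation maps ingredient names to as-fed inclusion percentages that
#' must total 100, and flags which ingredients are energy bearing. Mineral
#' fillers (premix, limestone, dicalcium phosphate, salt) are treated as
#' zero-energy, zero-organic-nutrient carriers: they dilute the diet but
#' contribute nothing to gross energy or analytes.
#'
#' @param diet_name diet label.
#' @param inclusions named numeric vector of as-fed inclusion percentages,
#'   summing to 100 within `1e-6`.
#' @param energy_bearing character vector of ingredient names (a subset of
#'   `names(inclusions)`) treated as energy contributors.
#' @return an object of class `formulation_spec`.
#' @examples
#' formulation_spec("corn 1 diet",
#'   c("corn 1" = 97.4, "premix" = 0.5, "limestone" = 0.9,
#'     "dicalcium phosphate" = 0.9, "NaCl" = 0.3),
#'   energy_bearing = "corn 1")
#' @export
formulation_spec <- function(diet_name, inclusions, energy_bearing) {
  if (is.null(names(inclusions)) || any(!nzchar(names(inclusions)))) {
    fe_stop("inclusions must be a fully named numeric vector",
            "feedenergy_invalid_formulation")
  }
  if (abs(sum(inclusions) - 100) > 1e-6) {
    fe_stop(sprintf("diet '%s': inclusions sum to %.8f, not 100",
                    diet_name, sum(inclusions)),
            "feedenergy_invalid_formulation")
  }
  if (any(inclusions < 0)) {
    fe_stop(sprintf("diet '%s': negative inclusion", diet_name),
            "feedenergy_invalid_formulation")
  }
  missing <- setdiff(energy_bearing, names(inclusions))
  if (length(missing)) {
    fe_stop(sprintf("diet '%s': energy_bearing ingredient(s) %s not in inclusions",
                    diet_name, paste(missing, collapse = ", ")),
            "feedenergy_invalid_formulation")
  }
  structure(list(diet_name = as.character(diet_name),
                 inclusions = inclusions,
                 energy_bearing = as.character(energy_bearing)),
            class = "formulation_spec")
}

#' @export
print.formulation_spec <- function(x, ...) {
  cat(sprintf("Diet '%s': %d ingredients, energy-bearing fraction %.4f\n",
              x$diet_name, length(x$inclusions),
              direct_inclusion_fraction(x)))
  for (nm in names(x$inclusions)) {
    cat(sprintf("  %-22s %6.2f%%%s\n", nm, x$inclusions[[nm]],
                if (nm %in% x$energy_bearing) "" else "  (filler)"))
  }
  invisible(x)
}

#' Energy-bearing inclusion fraction of a diet
#'
#' The fraction of the diet (as-fed mass) made up of energy-bearing
#' ingredients; the divisor of the direct method. For single-cereal diets
#' formulated at 97.4% cereal this is 0.974.
#'
#' @param spec a [formulation_spec()].
#' @return fraction in (0, 1].
#' @export
direct_inclusion_fraction <- function(spec) {
  stopifnot(inherits(spec, "formulation_spec"))
  sum(spec$inclusions[spec$energy_bearing]) / 100
}

#' Expected diet composition from its formulation
#'
#' Inclusion-weighted as-fed mixture of the ingredient profiles. Fillers
#' (non-energy-bearing ingredients) contribute mass at an assumed 100% dry
#' matter but zero gross energy and zero analytes, unless `filler_ash`
#' supplies ash concentrations for them.
#'
#' @param spec a [formulation_spec()].
#' @param panel ingredient panel data.frame; all energy-bearing ingredients
#'   must be present and share one basis.
#' @param filler_ash optional named vector, ash % (as-fed) of fillers.
#' @return a [nutrient_profile()] for the diet, on `as_fed` basis.
#' @export
expected_diet_profile <- function(spec, panel, filler_ash = NULL) {
  stopifnot(inherits(spec, "formulation_spec"), is.data.frame(panel))
  eb <- spec$energy_bearing
  missing <- setdiff(eb, panel$name)
  if (length(missing)) {
    fe_stop(sprintf("diet '%s': no profile for ingredient(s) %s",
                    spec$diet_name, paste(missing, collapse = ", ")),
            "feedenergy_unknown_ingredient")
  }
  if (length(unique(panel$basis[panel$name %in% eb])) != 1L) {
    fe_stop(sprintf("diet '%s': ingredient profiles mix bases", spec$diet_name),
            "feedenergy_basis_error")
  }
  acc <- setNames(numeric(length(NUTRIENT_FIELDS) + 2),
                  c("dm_pct", NUTRIENT_FIELDS, "ge_mj_per_kg"))
  for (nm in names(spec$inclusions)) {
    f <- spec$inclusions[[nm]] / 100
    if (f == 0) next
    if (nm %in% eb) {
      p <- convert_basis(panel_profile(panel, nm), "as_fed")
      for (field in names(acc)) acc[[field]] <- acc[[field]] + f * p[[field]]
    } else {
      acc[["dm_pct"]] <- acc[["dm_pct"]] + f * 100   # mineral fillers ~ dry
      if (!is.null(filler_ash) && nm %in% names(filler_ash)) {
        acc[["ash_pct"]] <- acc[["ash_pct"]] + f * filler_ash[[nm]]
      }
    }
  }
  nutrient_profile(name = spec$diet_name, basis = "as_fed",
                   dm_pct = acc[["dm_pct"]], ash_pct = acc[["ash_pct"]],
                   ee_pct = acc[["ee_pct"]], ndf_pct = acc[["ndf_pct"]],
                   adf_pct = acc[["adf_pct"]], cp_pct = acc[["cp_pct"]],
                   starch_pct = acc[["starch_pct"]],
                   ge_mj_per_kg = acc[["ge_mj_per_kg"]])
}

#' Replacement geometry for difference-method evaluation
#'
#' In the difference method a test ingredient replaces a fixed proportion of
#' the basal cereal: the test diet carries
#' `total_energy_fraction * replacement_fraction` of test ingredient and
#' `total_energy_fraction * (1 - replacement_fraction)` of basal cereal
#' (as-fed mass fractions). With the conventional 97.4% energy-bearing
#' inclusion and a 40% replacement these are 0.3896 and 0.5844.
#'
#' @param test_ingredient name of the ingredient under evaluation.
#' @param basal_ingredient name of the basal cereal being replaced.
#' @param basal_diet,test_diet diet names carrying the basal and test mixes.
#' @param total_energy_fraction energy-bearing fraction of both diets
#'   (default 0.974).
#' @param replacement_fraction proportion of the basal cereal replaced by
#'   the test ingredient, in (0, 1) (default 0.40).
#' @return an object of class `difference_design` with fields
#'   `test_fraction` and `basal_fraction`.
#' @examples
#' difference_design("rice 5", "corn 5", "corn 5 diet", "rice 5 diet")
#' @export
difference_design <- function(test_ingredient, basal_ingredient,
                              basal_diet, test_diet,
                              total_energy_fraction = 0.974,
                              replacement_fraction = 0.40) {
  if (!(is_num1(replacement_fraction) && replacement_fraction > 0 &&
        replacement_fraction < 1)) {
    fe_stop("replacement_fraction must lie in (0, 1)",
            "feedenergy_invalid_design")
  }
  if (!(is_num1(total_energy_fraction) && total_energy_fraction > 0 &&
        total_energy_fraction <= 1)) {
    fe_stop("total_energy_fraction must lie in (0, 1]",
            "feedenergy_invalid_design")
  }
  structure(list(
    test_ingredient = test_ingredient,
    basal_ingredient = basal_ingredient,
    basal_diet = basal_diet,
    test_diet = test_diet,
    total_energy_fraction = total_energy_fraction,
    replacement_fraction = replacement_fraction,
    test_fraction = total_energy_fraction * replacement_fraction,
    basal_fraction = total_energy_fraction * (1 - replacement_fraction)),
    class = "difference_design")
}

#' @export
print.difference_design <- function(x, ...) {
  cat(sprintf(
    "Difference design: %s replaces %.0f%% of %s (%s vs %s); fractions %0.4f / %0.4f\n",
    x$test_ingredient, 100 * x$replacement_fraction, x$basal_ingredient,
    x$test_diet, x$basal_diet, x$test_fraction, x$basal_fraction))
  invisible(x)
}
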