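# Core balance calculations: per-record diet DE/ME and ATTD, and direct-
# and difference-method ingredient values.
#
# Conventions. Energies are MJ, masses kg of dry matter over the collection
# window, concentrations % of DM. Diet-level DE/ME carry no inclusion
# correction; the energy-bearing inclusion (0.974 for conventional 97.4%
# cereal diets) divides only at the ingredient step. This is the only
# convention under which diet-level and ingredient-level result tables are
# mutually consistent.

KCAL_TO_MJ <- 4.184e-3  # 1 kcal = 4.184 kJ

#' Construct an energy result
#'
#' DE/ME pair for one diet or ingredient on a declared basis. ME cannot
#' physically exceed DE; records violating this are flagged (not rejected),
#' since measurement noise can produce them.
#'
#' @param level `"diet"` or `"ingredient"`.
#' @param name diet or ingredient name.
#' @param basis `"as_fed"` or `"dry_matter"`.
#' @param de_mj_per_kg,me_mj_per_kg digestible and metabolizable energy,
#'   MJ/kg on `basis`.
#' @param dm_pct dry matter % of the entity, needed for later basis
#'   conversion (optional, `NA` if unknown).
#' @return data.frame of class `energy_result` with one row per element,
#'   columns `level`, `name`, `basis`, `de_mj_per_kg`, `me_mj_per_kg`,
#'   `me_de_ratio_pct`, `dm_pct`, `flag_me_exceeds_de`.
#' @export
energy_result <- function(level, name, basis, de_mj_per_kg, me_mj_per_kg,
                          dm_pct = NA_real_) {
  level <- match.arg(level, c("diet", "ingredient"))
  check_basis(basis)
  out <- data.frame(
    level = level, name = as.character(name), basis = basis,
    de_mj_per_kg = de_mj_per_kg, me_mj_per_kg = me_mj_per_kg,
    me_de_ratio_pct = 100 * me_mj_per_kg / de_mj_per_kg,
    dm_pct = dm_pct,
    flag_me_exceeds_de = me_mj_per_kg > de_mj_per_kg,
    stringsAsFactors = FALSE)
  class(out) <- c("energy_result", "data.frame")
  out
}

#' @rdname convert_basis
#' @param dm_pct dry matter % used for the conversion; defaults to the
#'   `dm_pct` column carried by the result.
#' @export
convert_basis.energy_result <- function(x, target, dm_pct = x$dm_pct, ...) {
  check_basis(target)
  factor <- if (target == "as_fed") dm_pct / 100 else 100 / dm_pct
  scale <- ifelse(x$basis == target, 1, factor)
  if (any(is.na(scale))) {
    fe_stop("convert_basis: dm_pct unknown for some rows",
            "feedenergy_basis_error")
  }
  x$de_mj_per_kg <- x$de_mj_per_kg * scale
  x$me_mj_per_kg <- x$me_mj_per_kg * scale
  x$basis <- target
  x$dm_pct <- dm_pct
  x
}

#' Diet-level DE and ME from balance records
#'
#' For each record, DE = (GE intake - fecal GE) / feed intake and
#' ME = (GE intake - fecal GE - urinary GE) / feed intake, on dry-matter
#' basis (all inputs over the same collection window). No inclusion
#' correction is applied at diet level.
#'
#' @param records data.frame of balance records with columns `pig_id`,
#'   `period`, `diet_name`, `feed_intake_kg_dm`, `feces_output_kg_dm`,
#'   `ge_intake_mj`, `ge_feces_mj`, `ge_urine_mj`.
#' @return an [energy_result()] (level `"diet"`, basis `"dry_matter"`) with
#'   one row per record, carrying `pig_id` and `period` columns.
#' @examples
#' r <- data.frame(pig_id = 1, period = 1, diet_name = "d",
#'   feed_intake_kg_dm = 5, feces_output_kg_dm = 0.6,
#'   ge_intake_mj = 90, ge_feces_mj = 9, ge_urine_mj = 1.8)
#' diet_energy(r)  # DE 16.2, ME 15.84
#' @export
diet_energy <- function(records) {
  stopifnot(is.data.frame(records))
  if (any(records$feed_intake_kg_dm <= 0)) {
    fe_stop("diet_energy: feed_intake_kg_dm must be positive",
            "feedenergy_division_error")
  }
  de <- (records$ge_intake_mj - records$ge_feces_mj) / records$feed_intake_kg_dm
  me <- (records$ge_intake_mj - records$ge_feces_mj - records$ge_urine_mj) /
    records$feed_intake_kg_dm
  out <- energy_result("diet", records$diet_name, "dry_matter", de, me)
  out$pig_id <- records$pig_id
  out$period <- records$period
  out
}

#' Direct-method ingredient energy
#'
#' When the test ingredient is the sole energy source of its diet, the
#' ingredient's DE/ME is the diet value divided by the energy-bearing
#' inclusion fraction (0.974 for conventional diets). The ME/DE ratio is
#' preserved.
#'
#' @param diet_result an [energy_result()] at diet level.
#' @param inclusion energy-bearing inclusion fraction, in (0, 1].
#' @param ingredient_name name for the resulting ingredient rows; defaults
#'   to the diet names.
#' @param dm_pct ingredient dry matter %, attached for basis conversion.
#' @return an [energy_result()] at ingredient level, same basis.
#' @export
ingredient_energy_direct <- function(diet_result, inclusion,
                                     ingredient_name = diet_result$name,
                                     dm_pct = NA_real_) {
  if (any(!is.finite(inclusion)) || any(inclusion <= 0) || any(inclusion > 1)) {
    fe_stop("inclusion must lie in (0, 1]", "feedenergy_invalid_design")
  }
  out <- energy_result("ingredient", ingredient_name, diet_result$basis[1],
                       diet_result$de_mj_per_kg / inclusion,
                       diet_result$me_mj_per_kg / inclusion,
                       dm_pct = dm_pct)
  for (extra in intersect(c("pig_id", "period"), names(diet_result))) {
    out[[extra]] <- diet_result[[extra]]
  }
  out
}

#' Difference-method ingredient energy
#'
#' Solves for the test ingredient's DE/ME from the test diet's value and a
#' basal reference. Two readings are provided and the caller must choose:
#'
#' * `"contribution"` — the additive-mixture inverse: the test diet's
#'   energy (per kg diet) is the inclusion-weighted sum of ingredient
#'   contributions, so
#'   `DE_test = (DE_testdiet - basal_fraction * DE_basal_ingredient) /
#'   test_fraction`, with raw (uncorrected) diet values and the basal
#'   *ingredient* value as reference. Exact inverse of the mixing model;
#'   fractions must be mass fractions on the basis of the inputs (as-fed
#'   for the conventional 0.5844 / 0.3896 split).
#' * `"as_printed"` — the textbook substitution formula applied to
#'   inclusion-corrected diet values:
#'   `DE_test = (DE_testdiet/E - (DE_basaldiet/E) * (1 - R)) / test_fraction`
#'   with `E` the energy-bearing fraction (0.974) and `R` the replacement
#'   fraction (0.40).
#'
#' @param test_diet_result [energy_result()] rows for the test diet.
#' @param design a [difference_design()].
#' @param mode `"contribution"` or `"as_printed"`; no default is applied.
#' @param basal_reference for `"contribution"`: an [energy_result()] row at
#'   *ingredient* level for the basal cereal; for `"as_printed"`: the basal
#'   *diet* [energy_result()] row. Must share the test result's basis.
#' @param dm_pct test ingredient dry matter %, attached for conversion.
#' @return an [energy_result()] at ingredient level; negative estimates are
#'   possible with noisy inputs and are returned (flagged via
#'   `flag_me_exceeds_de` only when ME > DE).
#' @export
ingredient_energy_difference <- function(test_diet_result, design, mode,
                                         basal_reference, dm_pct = NA_real_) {
  mode <- match.arg(mode, c("contribution", "as_printed"))
  stopifnot(inherits(design, "difference_design"))
  if (design$test_fraction <= 0) {
    fe_stop("test_fraction must be positive", "feedenergy_invalid_design")
  }
  if (!identical(unique(basal_reference$basis), test_diet_result$basis[1])) {
    fe_stop("difference method: basal reference basis differs from test diet",
            "feedenergy_basis_error")
  }
  de_ref <- basal_reference$de_mj_per_kg[1]
  me_ref <- basal_reference$me_mj_per_kg[1]
  if (mode == "contribution") {
    de <- (test_diet_result$de_mj_per_kg - design$basal_fraction * de_ref) /
      design$test_fraction
    me <- (test_diet_result$me_mj_per_kg - design$basal_fraction * me_ref) /
      design$test_fraction
  } else {
    e <- design$total_energy_fraction
    r <- design$replacement_fraction
    de <- (test_diet_result$de_mj_per_kg / e - (de_ref / e) * (1 - r)) /
      design$test_fraction
    me <- (test_diet_result$me_mj_per_kg / e - (me_ref / e) * (1 - r)) /
      design$test_fraction
  }
  out <- energy_result("ingredient", design$test_ingredient,
                       test_diet_result$basis[1], de, me, dm_pct = dm_pct)
  for (extra in intersect(c("pig_id", "period"), names(test_diet_result))) {
    out[[extra]] <- test_diet_result[[extra]]
  }
  out
}

#' Diet-level apparent total tract digestibility
#'
#' ATTD (%) = 100 * (N_d * FI - N_f * FO) / (N_d * FI), where N_d and N_f
#' are the nutrient concentrations (% DM) of diet and feces and FI, FO the
#' DM intake and fecal output over the collection window.
#'
#' @param records balance-record data.frame (see [diet_energy()]) with
#'   concentration columns `dietconc_<nutrient>_pct` and
#'   `fecesconc_<nutrient>_pct`. Two nutrients bypass the concentration
#'   columns: `"DM"` uses the intake/output masses directly and `"GE"` uses
#'   the energy columns (`100 * (GE_i - GE_f) / GE_i`).
#' @param nutrient one of `"GE"`, `"DM"`, `"CP"`, `"NDF"`, `"ADF"`, `"ash"`,
#'   `"EE"`.
#' @return data.frame of class `digestibility_result`: columns `level`,
#'   `name`, `nutrient`, `attd_pct`, plus `pig_id`, `period`.
#' @export
diet_attd <- function(records, nutrient) {
  stopifnot(is.data.frame(records))
  fi <- records$feed_intake_kg_dm
  fo <- records$feces_output_kg_dm
  if (any(fi <= 0)) {
    fe_stop("diet_attd: feed_intake_kg_dm must be positive",
            "feedenergy_division_error")
  }
  if (identical(nutrient, "GE")) {
    attd <- 100 * (records$ge_intake_mj - records$ge_feces_mj) /
      records$ge_intake_mj
    out <- data.frame(level = "diet", name = records$diet_name,
                      nutrient = nutrient, attd_pct = attd,
                      pig_id = records$pig_id, period = records$period,
                      stringsAsFactors = FALSE)
    class(out) <- c("digestibility_result", "data.frame")
    return(out)
  }
  if (identical(nutrient, "DM")) {
    nd <- rep(100, nrow(records)); nf <- rep(100, nrow(records))
  } else {
    dcol <- paste0("dietconc_", nutrient, "_pct")
    fcol <- paste0("fecesconc_", nutrient, "_pct")
    if (!all(c(dcol, fcol) %in% names(records))) {
      fe_stop(sprintf("diet_attd: columns %s / %s missing", dcol, fcol),
              "feedenergy_missing_column")
    }
    nd <- records[[dcol]]; nf <- records[[fcol]]
    if (any(nd <= 0)) {
      fe_stop("diet_attd: diet nutrient concentration must be positive",
              "feedenergy_undefined_digestibility")
    }
  }
  attd <- 100 * (nd * fi - nf * fo) / (nd * fi)
  out <- data.frame(level = "diet", name = records$diet_name,
                    nutrient = nutrient, attd_pct = attd,
                    pig_id = records$pig_id, period = records$period,
                    stringsAsFactors = FALSE)
  class(out) <- c("digestibility_result", "data.frame")
  out
}

#' Direct-method ingredient ATTD
#'
#' Ingredient ATTD from a sole-source diet: the digested amount all comes
#' from the test ingredient, so `attd_ingredient = attd_diet / share`,
#' where `share` is the fraction of the diet's nutrient amount supplied by
#' the ingredient. With nutrient-free mineral fillers the share is 1 for
#' organic nutrients and gross energy — the ingredient ATTD then equals the
#' diet ATTD — while dry matter uses the ingredient's DM share of the diet.
#'
#' @param diet_attd_result a `digestibility_result` at diet level.
#' @param share ingredient's share of the diet's nutrient amount, (0, 1].
#' @param ingredient_name name for the output rows.
#' @return a `digestibility_result` at ingredient level.
#' @export
ingredient_attd_direct <- function(diet_attd_result, share,
                                   ingredient_name = diet_attd_result$name) {
  if (any(!is.finite(share)) || any(share <= 0) || any(share > 1)) {
    fe_stop("share must lie in (0, 1]", "feedenergy_invalid_design")
  }
  out <- diet_attd_result
  out$level <- "ingredient"
  out$name <- ingredient_name
  out$attd_pct <- diet_attd_result$attd_pct / share
  out
}

#' Difference-method ingredient ATTD
#'
#' Nutrient-contribution difference method: with `X` the test ingredient's
#' share of the test diet's nutrient amount and `B` the basal ingredient's
#' share,
#' `attd_test = (attd_testdiet - B * attd_basal_ingredient) / X`.
#' When the two energy-bearing ingredients supply the whole nutrient amount
#' `B = 1 - X` (the default); for dry matter, where mineral fillers also
#' contribute (indigestible) mass, pass the explicit basal share.
#' Estimates can fall outside \[0, 100\] with noisy inputs; they are
#' returned with `flag_out_of_range` set.
#'
#' @param test_diet_attd `digestibility_result` rows for the test diet.
#' @param basal_ingredient_attd scalar ATTD (%) of the basal ingredient for
#'   the same nutrient (typically its direct-method estimate).
#' @param test_share `X`, the test ingredient's share of the test diet's
#'   nutrient amount, in (0, 1].
#' @param basal_share `B`, the basal ingredient's share; defaults to
#'   `1 - test_share`.
#' @param ingredient_name name for the output rows.
#' @return a `digestibility_result` at ingredient level.
#' @export
ingredient_attd_difference <- function(test_diet_attd, basal_ingredient_attd,
                                       test_share,
                                       basal_share = 1 - test_share,
                                       ingredient_name = test_diet_attd$name) {
  if (!is_num1(test_share) || test_share <= 0 || test_share > 1) {
    fe_stop("test_share must lie in (0, 1]", "feedenergy_invalid_design")
  }
  if (!is_num1(basal_share) || basal_share < 0 ||
      basal_share + test_share > 1 + 1e-9) {
    fe_stop("basal_share must be non-negative with basal + test share <= 1",
            "feedenergy_invalid_design")
  }
  out <- test_diet_attd
  out$level <- "ingredient"
  out$name <- ingredient_name
  out$attd_pct <- (test_diet_attd$attd_pct -
                     basal_share * basal_ingredient_attd) / test_share
  out$flag_out_of_range <- out$attd_pct < 0 | out$attd_pct > 100
  out
}

#' Validate balance records
#'
#' Flags physically impossible records — non-positive intake, negative
#' masses or energies, or fecal + urinary energy exceeding intake energy.
#' Nothing is dropped; downstream steps may filter on the flags.
#'
#' @param records balance-record data.frame (see [diet_energy()]).
#' @return `records` with logical columns `flag_nonpositive_intake`,
#'   `flag_negative_value`, `flag_energy_balance` appended, and attribute
#'   `n_flagged`.
#' @export
validate_balance <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("pig_id", "period", "diet_name", "feed_intake_kg_dm",
              "feces_output_kg_dm", "ge_intake_mj", "ge_feces_mj",
              "ge_urine_mj")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    fe_stop(sprintf("balance table missing column(s): %s",
                    paste(missing, collapse = ", ")),
            "feedenergy_missing_column")
  }
  num <- c("feces_output_kg_dm", "ge_intake_mj", "ge_feces_mj", "ge_urine_mj")
  records$flag_nonpositive_intake <- records$feed_intake_kg_dm <= 0
  records$flag_negative_value <-
    Reduce(`|`, lapply(records[num], function(x) x < 0))
  records$flag_energy_balance <-
    records$ge_feces_mj + records$ge_urine_mj > records$ge_intake_mj
  attr(records, "n_flagged") <- sum(records$flag_nonpositive_intake |
                                      records$flag_negative_value |
                                      records$flag_energy_balance)
  records
}
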