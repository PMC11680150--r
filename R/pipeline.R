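# End-to-end orchestration: balance records -> diet results -> ingredient
# results (direct + difference) -> correlation screen -> prediction
# equations, with tabular report output.

#' Evaluate a digestion trial
#'
#' Runs the full calculation chain on per-pig-period balance records:
#' per-record diet DE/ME (dry-matter basis, converted as-fed with the diet
#' dry matter), per-record ATTD for every nutrient with concentration
#' columns, direct-method ingredient values for sole-cereal diets, and
#' difference-method values for replacement designs (basal references taken
#' as the basal ingredient's least-squares means). Per-record results are
#' aggregated to least-squares means with period adjustment.
#'
#' @param records balance records (see [read_balance_table()]).
#' @param panel ingredient composition panel.
#' @param formulations named list of [formulation_spec()]s covering every
#'   diet in `records`.
#' @param designs named list of [difference_design()]s (may be empty).
#' @param mode difference-method mode, `"contribution"` or `"as_printed"`;
#'   required whenever `designs` is non-empty.
#' @param diet_dm optional named vector of measured diet dry-matter %,
#'   overriding the formulation-derived values for basis conversion.
#' @param drop_flagged drop physically impossible records instead of
#'   keeping them (default keep).
#' @return list with `per_record` (long data.frame: `pig_id`, `period`,
#'   `diet_name`, `name`, `level`, `response`, `basis`, `value`),
#'   `diet_summary` and `ingredient_summary` (wide report tables),
#'   `validation` (flagged records).
#' @export
evaluate_trial <- function(records, panel, formulations, designs = list(),
                           mode = NULL, diet_dm = NULL,
                           drop_flagged = FALSE) {
  records <- validate_balance(records)
  flagged <- records[records$flag_nonpositive_intake |
                       records$flag_negative_value |
                       records$flag_energy_balance, , drop = FALSE]
  if (drop_flagged && nrow(flagged)) {
    records <- records[setdiff(rownames(records), rownames(flagged)), ,
                       drop = FALSE]
  }
  diets_used <- unique(records$diet_name)
  missing <- setdiff(diets_used, names(formulations))
  if (length(missing)) {
    fe_stop(sprintf("no formulation for diet(s): %s",
                    paste(missing, collapse = ", ")),
            "feedenergy_unknown_ingredient")
  }
  if (length(designs) && is.null(mode)) {
    fe_stop("difference designs supplied but no mode chosen", "feedenergy_invalid_design")
  }
  profiles <- lapply(formulations[diets_used], expected_diet_profile,
                     panel = panel)
  dm_of_diet <- vapply(profiles, `[[`, numeric(1), "dm_pct")
  if (!is.null(diet_dm)) {
    dm_of_diet[names(diet_dm)] <- diet_dm
  }

  nutrients <- c("GE", "DM",
                 intersect(SIM_NUTRIENTS,
                           sub("^dietconc_(.*)_pct$", "\\1",
                               grep("^dietconc_.*_pct$", names(records),
                                    value = TRUE))))

  # ---- per-record diet results --------------------------------------
  den_dm <- diet_energy(records)
  den_af <- convert_basis(den_dm, "as_fed",
                          dm_pct = unname(dm_of_diet[den_dm$name]))
  long <- rbind(energy_long(den_af, diet_of = den_af$name),
                energy_long(den_dm, diet_of = den_dm$name, ratio = TRUE))
  for (nu in nutrients) {
    att <- diet_attd(records, nu)
    long <- rbind(long, attd_long(att, diet_of = att$name, nutrient = nu))
  }

  # ---- ingredient results -------------------------------------------
  test_diets <- vapply(designs, `[[`, character(1), "test_diet")
  direct_diets <- setdiff(diets_used, test_diets)
  ing_long <- NULL
  for (dn in direct_diets) {
    spec <- formulations[[dn]]
    if (length(spec$energy_bearing) != 1L) {
      warning(sprintf(
        "diet '%s' has %d energy-bearing ingredients and no difference design; skipped at ingredient level",
        dn, length(spec$energy_bearing)))
      next
    }
    ing <- spec$energy_bearing
    ing_dm <- panel$dm_pct[match(ing, panel$name)]
    rows <- den_af[den_af$name == dn, , drop = FALSE]
    e_af <- ingredient_energy_direct(rows, direct_inclusion_fraction(spec),
                                     ingredient_name = ing, dm_pct = ing_dm)
    e_dm <- convert_basis(e_af, "dry_matter")
    ing_long <- rbind(ing_long,
                      energy_long(e_af, diet_of = dn),
                      energy_long(e_dm, diet_of = dn, ratio = TRUE))
    shares <- nutrient_shares(spec, panel, profiles[[dn]])
    for (nu in nutrients) {
      att <- long[long$level == "diet" & long$response == paste0("attd_", nu) &
                    long$name == dn, , drop = FALSE]
      att_res <- data.frame(level = "diet", name = att$name, nutrient = nu,
                            attd_pct = att$value, pig_id = att$pig_id,
                            period = att$period, stringsAsFactors = FALSE)
      ing_att <- ingredient_attd_direct(att_res, shares[[ing]][[nu]],
                                        ingredient_name = ing)
      ing_long <- rbind(ing_long,
                        attd_long(ing_att, diet_of = dn, nutrient = nu))
    }
  }

  # ---- difference-method ingredients --------------------------------
  for (ds in designs) {
    basal_ing <- ds$basal_ingredient
    ref_rows <- function(resp, basis) {
      sub <- ing_long[ing_long$name == basal_ing &
                        ing_long$response == resp & ing_long$basis == basis, ,
                      drop = FALSE]
      if (!nrow(sub)) {
        fe_stop(sprintf("difference design '%s': basal ingredient '%s' has no direct-method results",
                        ds$test_ingredient, basal_ing),
                "feedenergy_invalid_design")
      }
      diet_lsmeans_value(sub)
    }
    rows <- den_af[den_af$name == ds$test_diet, , drop = FALSE]
    if (!nrow(rows)) {
      fe_stop(sprintf("difference design '%s': no records for test diet '%s'",
                      ds$test_ingredient, ds$test_diet),
              "feedenergy_invalid_design")
    }
    basal_ref <- if (mode == "contribution") {
      energy_result("ingredient", basal_ing, "as_fed",
                    ref_rows("de_mj_per_kg", "as_fed"),
                    ref_rows("me_mj_per_kg", "as_fed"))
    } else {
      basal_rows <- den_af[den_af$name == ds$basal_diet, , drop = FALSE]
      energy_result("diet", ds$basal_diet, "as_fed",
                    diet_lsmeans_value(energy_long(basal_rows,
                                                   diet_of = basal_rows$name),
                                       "de_mj_per_kg"),
                    diet_lsmeans_value(energy_long(basal_rows,
                                                   diet_of = basal_rows$name),
                                       "me_mj_per_kg"))
    }
    ing_dm <- panel$dm_pct[match(ds$test_ingredient, panel$name)]
    e_af <- ingredient_energy_difference(rows, ds, mode = mode,
                                         basal_reference = basal_ref,
                                         dm_pct = ing_dm)
    e_dm <- convert_basis(e_af, "dry_matter")
    ing_long <- rbind(ing_long,
                      energy_long(e_af, diet_of = ds$test_diet),
                      energy_long(e_dm, diet_of = ds$test_diet, ratio = TRUE))
    spec <- formulations[[ds$test_diet]]
    shares <- nutrient_shares(spec, panel, profiles[[ds$test_diet]])
    for (nu in nutrients) {
      att <- long[long$level == "diet" & long$response == paste0("attd_", nu) &
                    long$name == ds$test_diet, , drop = FALSE]
      att_res <- data.frame(level = "diet", name = att$name, nutrient = nu,
                            attd_pct = att$value, pig_id = att$pig_id,
                            period = att$period, stringsAsFactors = FALSE)
      basal_att <- diet_lsmeans_value(
        ing_long[ing_long$name == basal_ing &
                   ing_long$response == paste0("attd_", nu), , drop = FALSE])
      ing_att <- ingredient_attd_difference(
        att_res, basal_att,
        test_share = shares[[ds$test_ingredient]][[nu]],
        basal_share = shares[[basal_ing]][[nu]],
        ingredient_name = ds$test_ingredient)
      ing_long <- rbind(ing_long,
                        attd_long(ing_att, diet_of = ds$test_diet,
                                  nutrient = nu))
    }
  }

  per_record <- rbind(long, ing_long)
  list(per_record = per_record,
       diet_summary = summarize_results(long),
       ingredient_summary = summarize_results(ing_long),
       validation = flagged)
}

# long-format helpers ------------------------------------------------

energy_long <- function(er, diet_of, ratio = FALSE) {
  base <- data.frame(pig_id = er$pig_id, period = er$period,
                     diet_name = diet_of, name = er$name, level = er$level,
                     basis = er$basis, stringsAsFactors = FALSE)
  out <- rbind(
    cbind(base, response = "de_mj_per_kg", value = er$de_mj_per_kg),
    cbind(base, response = "me_mj_per_kg", value = er$me_mj_per_kg))
  if (ratio) {
    out <- rbind(out, cbind(base, response = "me_de_ratio_pct",
                            value = er$me_de_ratio_pct))
  }
  out
}

attd_long <- function(att, diet_of, nutrient) {
  data.frame(pig_id = att$pig_id, period = att$period, diet_name = diet_of,
             name = att$name, level = att$level, basis = "dry_matter",
             response = paste0("attd_", nutrient),
             value = att$attd_pct, stringsAsFactors = FALSE)
}

# ls-mean of the (single-entity) long rows for one response
diet_lsmeans_value <- function(sub, response = unique(sub$response)) {
  sub <- sub[sub$response == response[1], , drop = FALSE]
  mean(tapply(sub$value, sub$period, mean))
}

# per-ingredient share of each nutrient amount in a diet (as-fed)
nutrient_shares <- function(spec, panel, diet_profile) {
  conc_field <- c(CP = "cp_pct", NDF = "ndf_pct", ADF = "adf_pct",
                  ash = "ash_pct", EE = "ee_pct", GE = "ge_mj_per_kg",
                  DM = "dm_pct")
  out <- list()
  for (ing in spec$energy_bearing) {
    p_af <- convert_basis(panel_profile(panel, ing), "as_fed")
    f <- spec$inclusions[[ing]] / 100
    shares <- list()
    for (nu in names(conc_field)) {
      total <- diet_profile[[conc_field[[nu]]]]
      shares[[nu]] <- if (total > 0) {
        min(1, f * p_af[[conc_field[[nu]]]] / total)
      } else NA_real_
    }
    out[[ing]] <- shares
  }
  out
}

#' Aggregate long per-record results into a wide report table
#'
#' One row per (response, basis): diet (or ingredient) least-squares means
#' across the columns plus the average SEM and the overall F-test p-value.
#'
#' @param long long per-record data.frame from [evaluate_trial()].
#' @return wide data.frame.
#' @export
summarize_results <- function(long) {
  keys <- unique(long[c("response", "basis")])
  entities <- unique(long$name)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- long[long$response == keys$response[i] &
                  long$basis == keys$basis[i], , drop = FALSE]
    sub$diet_name <- sub$name   # aggregate by entity, adjusted for period
    ls <- diet_lsmeans(sub, "value")
    vals <- setNames(as.list(ls$table$lsmean[match(entities, ls$table$name)]),
                     entities)
    cbind(data.frame(response = keys$response[i], basis = keys$basis[i],
                     stringsAsFactors = FALSE),
          as.data.frame(vals, check.names = FALSE, optional = TRUE),
          data.frame(sem = ls$sem, p_value = ls$p_value))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ingredient-level value table for correlation and regression
#'
#' Joins the panel's chemical composition (converted to `basis`) with the
#' estimated ingredient DE/ME from an evaluation summary, using canonical
#' column names `DM`, `ash`, `EE`, `NDF`, `ADF`, `CP`, `starch`, `GE`,
#' `DE`, `ME`.
#'
#' @param ingredient_summary wide summary from [evaluate_trial()], or the
#'   packaged [reference_ingredient_results()].
#' @param panel ingredient composition panel.
#' @param basis basis for both composition and energy values.
#' @return data.frame, one row per ingredient, plus a `name` column and a
#'   `basis` attribute-carrying column.
#' @export
ingredient_value_table <- function(ingredient_summary, panel,
                                   basis = "dry_matter") {
  check_basis(basis)
  ings <- setdiff(names(ingredient_summary),
                  c("response", "basis", "sem", "p_value"))
  ings <- ings[ings %in% panel$name]
  rows <- lapply(ings, function(nm) {
    p <- convert_basis(panel_profile(panel, nm), basis)
    data.frame(name = nm, basis = basis, DM = p$dm_pct, ash = p$ash_pct,
               EE = p$ee_pct, NDF = p$ndf_pct, ADF = p$adf_pct, CP = p$cp_pct,
               starch = p$starch_pct, GE = p$ge_mj_per_kg,
               DE = reference_value(ingredient_summary, "de_mj_per_kg",
                                    basis, nm),
               ME = reference_value(ingredient_summary, "me_mj_per_kg",
                                    basis, nm),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit the standard DE and ME prediction-equation paths
#'
#' Stepwise DE on the chemical analytes and stepwise ME on the analytes
#' plus DE, mirroring the conventional candidate sets.
#'
#' @param values ingredient value table from [ingredient_value_table()].
#' @param sle,sls stepwise entry/stay thresholds (default 0.15, the
#'   classical stepwise default).
#' @return list with `DE` and `ME` [stepwise_fit()] paths.
#' @export
fit_prediction_equations <- function(values, sle = 0.15, sls = 0.15) {
  basis <- unique(values$basis)
  analytes <- c("DM", "ash", "EE", "NDF", "ADF", "CP", "starch", "GE")
  list(DE = stepwise_fit(values, "DE", analytes, sle = sle, sls = sls,
                         basis = basis),
       ME = stepwise_fit(values, "ME", c(analytes, "DE"), sle = sle,
                         sls = sls, basis = basis))
}

#' Pipeline configuration
#'
#' @param ingredient_table,diet_table,balance_table input CSV paths.
#' @param out_dir output directory (created if absent).
#' @param mode difference-method mode; the pipeline defaults to
#'   `"contribution"` and logs the choice.
#' @param basis basis for correlations and equations.
#' @param sle,sls stepwise thresholds.
#' @param seed integer seed recorded in the log (the evaluation chain
#'   itself is deterministic).
#' @param energy_unit `"mj"` or `"kcal"` for the balance table.
#' @param drop_flagged drop physically impossible records.
#' @param round_digits decimals for the human-readable report.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(ingredient_table, diet_table, balance_table,
                            out_dir, mode = "contribution",
                            basis = "dry_matter", sle = 0.15, sls = 0.15,
                            seed = 1L, energy_unit = "mj",
                            drop_flagged = FALSE, round_digits = 2) {
  for (f in c(ingredient_table, diet_table, balance_table)) {
    if (!file.exists(f)) {
      fe_stop(sprintf("input file does not exist: %s", f),
              "feedenergy_config_error")
    }
  }
  mode <- match.arg(mode, c("contribution", "as_printed"))
  check_basis(basis)
  structure(list(ingredient_table = ingredient_table,
                 diet_table = diet_table, balance_table = balance_table,
                 out_dir = out_dir, mode = mode, basis = basis, sle = sle,
                 sls = sls, seed = as.integer(seed),
                 energy_unit = energy_unit, drop_flagged = drop_flagged,
                 round_digits = round_digits),
            class = "pipeline_config")
}

#' Run the full evaluation pipeline
#'
#' Reads the three input tables, evaluates the trial (difference designs
#' are auto-detected from two-cereal formulations: the lower-inclusion
#' energy-bearing ingredient is the test ingredient), screens correlations,
#' fits prediction equations, and writes the report bundle to
#' `config$out_dir`: `diet_results.csv`, `ingredient_results.csv`,
#' `correlations_r.csv`, `correlations_p.csv`, `equations.txt`,
#' `validation_log.txt` and a rounded `report.txt`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with all intermediate objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  panel <- read_ingredient_table(config$ingredient_table)
  formulations <- read_diet_table(config$diet_table)
  records <- read_balance_table(config$balance_table,
                                energy_unit = config$energy_unit)

  designs <- detect_difference_designs(formulations)
  log_lines <- c(sprintf("feedenergy pipeline (seed %d)", config$seed),
                 sprintf("difference-method mode: %s", config$mode),
                 sprintf("records: %d; difference designs: %s",
                         nrow(records),
                         if (length(designs))
                           paste(names(designs), collapse = ", ")
                         else "none"))

  ev <- evaluate_trial(records, panel, formulations, designs = designs,
                       mode = config$mode,
                       drop_flagged = config$drop_flagged)
  log_lines <- c(log_lines,
                 sprintf("flagged records: %d (%s)", nrow(ev$validation),
                         if (config$drop_flagged) "dropped" else "kept"))

  values <- ingredient_value_table(ev$ingredient_summary, panel,
                                   basis = config$basis)
  corr <- pearson_matrix(values, c("DM", "ash", "EE", "NDF", "ADF", "CP",
                                   "starch", "GE", "DE", "ME"))
  eqs <- fit_prediction_equations(values, sle = config$sle, sls = config$sls)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  write_result_table(ev$diet_summary, out("diet_results.csv"))
  write_result_table(ev$ingredient_summary, out("ingredient_results.csv"))
  write_result_table(matrix_df(corr$r, corr$variables),
                     out("correlations_r.csv"))
  write_result_table(matrix_df(corr$p, corr$variables),
                     out("correlations_p.csv"))
  write_equation_registry(c(eqs$DE, eqs$ME), out("equations.txt"))
  writeLines(log_lines, out("validation_log.txt"))
  writeLines(render_report(ev, corr, eqs, config$round_digits),
             out("report.txt"))
  invisible(list(panel = panel, formulations = formulations,
                 records = records, designs = designs, evaluation = ev,
                 values = values, correlations = corr, equations = eqs,
                 log = log_lines))
}

# a formulation with two energy-bearing cereals is read as a replacement
# diet: the larger inclusion is the basal, the smaller the test ingredient
detect_difference_designs <- function(formulations) {
  designs <- list()
  for (spec in formulations) {
    eb <- spec$energy_bearing
    if (length(eb) != 2L) next
    incl <- spec$inclusions[eb]
    test <- eb[which.min(incl)]
    basal <- eb[which.max(incl)]
    basal_diet <- NULL
    for (other in formulations) {
      if (identical(other$energy_bearing, basal)) basal_diet <- other$diet_name
    }
    if (is.null(basal_diet)) {
      warning(sprintf("diet '%s': no sole-source basal diet for '%s'; skipped",
                      spec$diet_name, basal))
      next
    }
    total <- sum(incl) / 100
    designs[[test]] <- difference_design(
      test, basal, basal_diet, spec$diet_name,
      total_energy_fraction = total,
      replacement_fraction = (incl[[test]] / 100) / total)
  }
  designs
}

matrix_df <- function(m, variables) {
  cbind(data.frame(variable = variables, stringsAsFactors = FALSE),
        as.data.frame(m, check.names = FALSE, optional = TRUE))
}

render_report <- function(ev, corr, eqs, digits) {
  fmt_table <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.numeric(col)) round_half_up(col, digits) else col
    })
    c(utils::capture.output(print(df, row.names = FALSE)), "")
  }
  c("Diet-level results (least-squares means)",
    fmt_table(ev$diet_summary),
    "Ingredient-level results (least-squares means)",
    fmt_table(ev$ingredient_summary),
    "Correlation screen",
    utils::capture.output(print(corr)), "",
    "Prediction equations (stepwise paths)",
    utils::capture.output(print(eqs$DE)),
    utils::capture.output(print(eqs$ME)))
}
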