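# Delimited-text interfaces. All tables are plain CSV, UTF-8, decimal
# point, header mandatory; lines starting with '#' are comments.

INGREDIENT_COLUMNS <- c("name", "basis", "dm_pct", "ash_pct", "ee_pct",
                        "ndf_pct", "adf_pct", "cp_pct", "starch_pct",
                        "ge_mj_per_kg")

#' Read an ingredient composition table
#'
#' One row per ingredient with columns
#' `name,basis,dm_pct,ash_pct,ee_pct,ndf_pct,adf_pct,cp_pct,starch_pct,ge_mj_per_kg`.
#' Every row is validated through [nutrient_profile()].
#'
#' @param path CSV path.
#' @return data.frame (ingredient panel).
#' @export
read_ingredient_table <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(INGREDIENT_COLUMNS, names(tab))
  if (length(missing)) {
    fe_stop(sprintf("%s: missing column(s) %s", path,
                    paste(missing, collapse = ", ")),
            "feedenergy_parse_error")
  }
  for (i in seq_len(nrow(tab))) {
    do.call(nutrient_profile, as.list(tab[i, INGREDIENT_COLUMNS]))
  }
  tab
}

#' Read a diet formulation table
#'
#' Long format `diet_name,ingredient,inclusion_pct,energy_bearing` (0/1).
#'
#' @param path CSV path.
#' @return named list of [formulation_spec()]s.
#' @export
read_diet_table <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("diet_name", "ingredient", "inclusion_pct", "energy_bearing")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    fe_stop(sprintf("%s: missing column(s) %s", path,
                    paste(missing, collapse = ", ")),
            "feedenergy_parse_error")
  }
  specs <- lapply(split(tab, tab$diet_name), function(d) {
    formulation_spec(d$diet_name[1],
                     setNames(d$inclusion_pct, d$ingredient),
                     energy_bearing = d$ingredient[d$energy_bearing == 1])
  })
  specs[unique(tab$diet_name)]
}

#' Read a balance-record table
#'
#' Columns `pig_id,period,diet_name,feed_intake_kg_dm,feces_output_kg_dm,
#' ge_intake_mj,ge_feces_mj,ge_urine_mj` plus optional paired
#' `dietconc_<nutrient>_pct` / `fecesconc_<nutrient>_pct` columns. Records
#' measured in kcal can be ingested with `energy_unit = "kcal"`; they are
#' converted to MJ (1 kcal = 4.184 kJ) and a message is emitted.
#'
#' @param path CSV path.
#' @param energy_unit `"mj"` (default) or `"kcal"`.
#' @return validated balance-record data.frame (see [validate_balance()]).
#' @export
read_balance_table <- function(path, energy_unit = c("mj", "kcal")) {
  energy_unit <- match.arg(energy_unit)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    fe_stop(sprintf("%s: balance table is empty", path),
            "feedenergy_parse_error")
  }
  if (energy_unit == "kcal") {
    for (col in c("ge_intake_mj", "ge_feces_mj", "ge_urine_mj")) {
      kcol <- sub("_mj$", "_kcal", col)
      if (!kcol %in% names(tab)) {
        fe_stop(sprintf("%s: expected column %s for kcal input", path, kcol),
                "feedenergy_parse_error")
      }
      tab[[col]] <- tab[[kcol]] * KCAL_TO_MJ
      tab[[kcol]] <- NULL
    }
    message("energies converted from kcal to MJ (1 kcal = 4.184 kJ)")
  }
  validate_balance(tab)
}

#' Write a result table
#'
#' Unrounded CSV (full double precision); rounding belongs to the
#' human-readable report only.
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
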