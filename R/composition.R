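# Nutrient-composition data model and basis algebra.
#
# Concentrations are stored on the 0-100 percent scale as printed in feed
# tables, never as fractions. Every profile carries an explicit basis
# (as_fed or dry_matter); cross-table operations fail loudly on a mismatch
# rather than converting silently, because mixed bases are the main source
# of error when combining composition tables with energy results.

NUTRIENT_FIELDS <- c("ash_pct", "ee_pct", "ndf_pct", "adf_pct",
                     "cp_pct", "starch_pct")
PROFILE_FIELDS <- c("name", "basis", "dm_pct", NUTRIENT_FIELDS, "ge_mj_per_kg")

#' Create a nutrient profile
#'
#' A nutrient profile holds one ingredient's (or diet's) proximate
#' composition and gross energy on a declared basis. Dry matter (`dm_pct`)
#' is always expressed relative to fresh weight; all other analytes are on
#' `basis`.
#'
#' @param name ingredient or diet name.
#' @param basis `"as_fed"` or `"dry_matter"` — the basis of the analyte
#'   concentrations and of `ge_mj_per_kg`.
#' @param dm_pct dry matter, percent of fresh weight, in (0, 100].
#' @param ash_pct,ee_pct,ndf_pct,adf_pct,cp_pct,starch_pct ash, ether
#'   extract, neutral detergent fiber, acid detergent fiber, crude protein
#'   and starch, percent on `basis`, each in \[0, 100\].
#' @param ge_mj_per_kg gross energy, MJ/kg on `basis`, > 0.
#' @return an object of class `nutrient_profile`.
#' @examples
#' corn <- nutrient_profile("corn 1", "dry_matter", dm_pct = 87.01,
#'   ash_pct = 1.36, ee_pct = 3.62, ndf_pct = 12.94, adf_pct = 3.42,
#'   cp_pct = 8.11, starch_pct = 65.85, ge_mj_per_kg = 18.43)
#' convert_basis(corn, "as_fed")
#' @export
nutrient_profile <- function(name, basis, dm_pct, ash_pct, ee_pct, ndf_pct,
                             adf_pct, cp_pct, starch_pct, ge_mj_per_kg) {
  check_basis(basis)
  p <- structure(
    list(name = as.character(name), basis = basis, dm_pct = dm_pct,
         ash_pct = ash_pct, ee_pct = ee_pct, ndf_pct = ndf_pct,
         adf_pct = adf_pct, cp_pct = cp_pct, starch_pct = starch_pct,
         ge_mj_per_kg = ge_mj_per_kg),
    class = "nutrient_profile")
  validate_profile(p)
}

#' Validate a nutrient profile
#'
#' Checks range invariants: `dm_pct` in (0, 100], analyte percentages in
#' \[0, 100\], positive gross energy, and (on dry-matter basis) that the
#' non-overlapping fractions starch + CP + EE + ash do not exceed 100.
#' NDF and ADF are excluded from the closure check because they overlap
#' other fractions and each other.
#'
#' @param p a `nutrient_profile`.
#' @param tol tolerance for the fraction-closure check, percentage points.
#' @return `p`, invisibly usable, after passing all checks.
#' @export
validate_profile <- function(p, tol = 1e-6) {
  stopifnot(inherits(p, "nutrient_profile"))
  num <- unlist(p[c("dm_pct", NUTRIENT_FIELDS, "ge_mj_per_kg")])
  if (!all(vapply(num, is_num1, logical(1)))) {
    fe_stop(sprintf("profile '%s': all numeric fields must be finite scalars",
                    p$name), "feedenergy_invalid_profile")
  }
  if (p$dm_pct <= 0 || p$dm_pct > 100) {
    fe_stop(sprintf("profile '%s': dm_pct must be in (0, 100], got %g",
                    p$name, p$dm_pct), "feedenergy_invalid_profile")
  }
  comp <- unlist(p[NUTRIENT_FIELDS])
  if (any(comp < 0 | comp > 100)) {
    fe_stop(sprintf("profile '%s': analyte percentages must lie in [0, 100]",
                    p$name), "feedenergy_invalid_profile")
  }
  if (p$ge_mj_per_kg <= 0) {
    fe_stop(sprintf("profile '%s': ge_mj_per_kg must be positive", p$name),
            "feedenergy_invalid_profile")
  }
  if (p$basis == "dry_matter") {
    closure <- p$starch_pct + p$cp_pct + p$ee_pct + p$ash_pct
    if (closure > 100 + tol) {
      fe_stop(sprintf(
        "profile '%s': starch + CP + EE + ash = %.3f%% exceeds 100%% on DM basis",
        p$name, closure), "feedenergy_invalid_profile")
    }
  }
  p
}

#' Convert a profile between as-fed and dry-matter bases
#'
#' Analyte concentrations and gross energy scale by the dry-matter fraction:
#' going to `as_fed` multiplies by `dm_pct / 100`, going to `dry_matter`
#' divides. `dm_pct` itself (percent of fresh weight) and the name are
#' unchanged; converting to the current basis is a no-op. The conversion is
#' exactly invertible.
#'
#' @param x object carrying a basis (a [nutrient_profile()] or an
#'   [energy_result()]).
#' @param target `"as_fed"` or `"dry_matter"`.
#' @param ... passed to methods.
#' @return the converted object.
#' @export
convert_basis <- function(x, target, ...) UseMethod("convert_basis")

#' @rdname convert_basis
#' @export
convert_basis.nutrient_profile <- function(x, target, ...) {
  check_basis(target)
  validate_profile(x)
  if (identical(x$basis, target)) return(x)
  f <- x$dm_pct / 100
  scale <- if (target == "as_fed") f else 1 / f
  for (field in c(NUTRIENT_FIELDS, "ge_mj_per_kg")) {
    x[[field]] <- x[[field]] * scale
  }
  x$basis <- target
  validate_profile(x)
}

#' @export
print.nutrient_profile <- function(x, ...) {
  cat(sprintf("Nutrient profile: %s (%s basis)\n", x$name,
              sub("_", " ", x$basis)))
  cat(sprintf("  DM %.2f%% | ash %.2f | EE %.2f | NDF %.2f | ADF %.2f | CP %.2f | starch %.2f %%\n",
              x$dm_pct, x$ash_pct, x$ee_pct, x$ndf_pct, x$adf_pct,
              x$cp_pct, x$starch_pct))
  cat(sprintf("  GE %.2f MJ/kg\n", x$ge_mj_per_kg))
  invisible(x)
}

#' @export
as.data.frame.nutrient_profile <- function(x, ...) {
  as.data.frame(x[PROFILE_FIELDS], stringsAsFactors = FALSE)
}

#' Coefficient-of-variation summary of a numeric vector
#'
#' Descriptive summary used for ingredient panels: n, mean, sample standard
#' deviation (n - 1 denominator) and CV as a percentage (100 * sd / mean).
#' The CV is invariant under uniform rescaling of the input.
#'
#' @param values numeric vector, length >= 2, with nonzero mean.
#' @return an object of class `summary_stats` with fields `n`, `mean`, `sd`,
#'   `cv_pct`.
#' @examples
#' cv_summary(c(1, 2, 3))  # cv_pct = 50
#' @export
cv_summary <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    fe_stop("cv_summary needs at least 2 numeric values",
            "feedenergy_insufficient_data")
  }
  if (anyNA(values)) {
    fe_stop("cv_summary: missing values are not allowed",
            "feedenergy_insufficient_data")
  }
  m <- mean(values)
  if (m == 0) {
    fe_stop("cv_summary: CV undefined for zero mean", "feedenergy_undefined_cv")
  }
  s <- stats::sd(values)
  structure(list(n = length(values), mean = m, sd = s, cv_pct = 100 * s / m),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.4g, sd = %.4g, CV = %.2f%%\n",
              x$n, x$mean, x$sd, x$cv_pct))
  invisible(x)
}

#' Per-analyte CV summaries across an ingredient panel
#'
#' Mirrors the CV column of an ingredient-composition table: one
#' [cv_summary()] per analyte over the rows of a panel.
#'
#' @param panel data.frame in the ingredient-table layout (see
#'   [read_ingredient_table()]); all rows must share one basis.
#' @param analytes columns to summarise; defaults to every analyte.
#' @return data.frame with columns `analyte`, `n`, `mean`, `sd`, `cv_pct`.
#' @export
panel_cv <- function(panel, analytes = c("dm_pct", NUTRIENT_FIELDS,
                                         "ge_mj_per_kg")) {
  stopifnot(is.data.frame(panel))
  if (length(unique(panel$basis)) != 1L) {
    fe_stop("panel_cv: panel mixes bases; convert first",
            "feedenergy_basis_error")
  }
  rows <- lapply(analytes, function(a) {
    s <- cv_summary(panel[[a]])
    data.frame(analyte = a, n = s$n, mean = s$mean, sd = s$sd,
               cv_pct = s$cv_pct, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract one ingredient's profile from a panel data.frame
#'
#' @param panel ingredient panel (see [read_ingredient_table()]).
#' @param name ingredient name to extract.
#' @return a [nutrient_profile()].
#' @export
panel_profile <- function(panel, name) {
  i <- match(name, panel$name)
  if (is.na(i)) {
    fe_stop(sprintf("ingredient '%s' not found in panel", name),
            "feedenergy_unknown_ingredient")
  }
  do.call(nutrient_profile, as.list(panel[i, PROFILE_FIELDS]))
}
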