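# Design-aware aggregation: least-squares means for row-column trials.

#' Create / validate a trial design
#'
#' A design is the (pig, period) -> diet assignment of a row-column trial.
#' For a proper Youden arrangement each diet occurs exactly once per period,
#' at most once per pig, and with equal replication overall.
#'
#' @param assignment data.frame with columns `pig_id`, `period`,
#'   `diet_name`, one row per cell.
#' @return object of class `trial_design` (the assignment with counts
#'   attached).
#' @export
trial_design <- function(assignment) {
  stopifnot(is.data.frame(assignment),
            all(c("pig_id", "period", "diet_name") %in% names(assignment)))
  structure(assignment, class = c("trial_design", "data.frame"))
}

#' @rdname trial_design
#' @param design a `trial_design`.
#' @return `validate_design()`: `design` invisibly; errors if the
#'   arrangement is not a proper Youden rectangle.
#' @export
validate_design <- function(design) {
  per_period <- table(design$diet_name, design$period)
  if (any(per_period != 1)) {
    fe_stop("design: each diet must occur exactly once per period",
            "feedenergy_invalid_design")
  }
  per_pig <- table(design$diet_name, design$pig_id)
  if (any(per_pig > 1)) {
    fe_stop("design: a diet may occur at most once per pig",
            "feedenergy_invalid_design")
  }
  reps <- table(design$diet_name)
  if (length(unique(reps)) != 1L) {
    fe_stop("design: diets must be equally replicated",
            "feedenergy_invalid_design")
  }
  invisible(design)
}

#' Least-squares means per diet
#'
#' Fits a fixed-effects two-way model `response ~ diet + period` by ordinary
#' least squares and reports the diet least-squares means (period-adjusted
#' means over a uniform period grid), their standard errors, and the overall
#' diet-effect F-test. With one observation per pig-period cell and a
#' balanced row-column arrangement, modelling period as a fixed factor
#' yields the same diet means a random-period fit would; see the package
#' vignette for the rationale.
#'
#' @param results data.frame with columns `diet_name`, `period` and the
#'   response; typically an [energy_result()] or `digestibility_result`
#'   carrying per-record values.
#' @param response name of the response column (e.g. `"de_mj_per_kg"`).
#' @return object of class `lsmeans_result`: list with `response`, `table`
#'   (data.frame `name`, `lsmean`, `se`), `sem` (average standard error of a
#'   mean, the single value conventionally tabulated), `df` (residual
#'   degrees of freedom), `p_value` (overall diet F-test), and `n_per_diet`.
#' @export
diet_lsmeans <- function(results, response) {
  stopifnot(is.data.frame(results), response %in% names(results))
  d <- data.frame(y = results[[response]],
                  diet = factor(results$diet_name),
                  period = factor(results$period))
  if (nlevels(d$diet) < 2L) {
    fe_stop("diet_lsmeans needs at least 2 diets", "feedenergy_invalid_design")
  }
  fit <- stats::lm(y ~ diet + period, data = d)
  if (anyNA(coef(fit)[grep("^diet", names(coef(fit)))])) {
    fe_stop("design is disconnected: diet means are not estimable",
            "feedenergy_estimability_error")
  }
  emm <- emmeans::emmeans(fit, "diet")
  emm_df <- as.data.frame(emm)
  tab <- data.frame(name = as.character(emm_df$diet),
                    lsmean = emm_df$emmean, se = emm_df$SE,
                    stringsAsFactors = FALSE)
  an <- stats::anova(fit)
  structure(list(
    response = response,
    table = tab,
    sem = mean(tab$se),
    df = fit$df.residual,
    p_value = an[["Pr(>F)"]][rownames(an) == "diet"],
    n_per_diet = as.integer(table(d$diet))),
    class = "lsmeans_result")
}

#' @export
print.lsmeans_result <- function(x, ...) {
  cat(sprintf("LS means for %s (SEM %.4g, residual df %d, diet p = %.3g%s)\n",
              x$response, x$sem, x$df, x$p_value,
              significance_label(x$p_value)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# Convention for annotating output: significant below 0.05,
# tendency in [0.05, 0.10).
significance_label <- function(p) {
  ifelse(p < 0.05, ", significant",
         ifelse(p < 0.10, ", tendency", ""))
}

#' Univariate outlier screen
#'
#' Reports studentized-style z-scores of a response within each diet
#' (deviation from the diet mean over the pooled residual SD). Nothing is
#' removed; the list supports manual review.
#'
#' @param results data.frame with `diet_name` and the response column.
#' @param response response column name.
#' @param threshold |z| above which a record is listed (default 3).
#' @return data.frame of flagged rows with a `z` column (possibly empty).
#' @export
outlier_screen <- function(results, response, threshold = 3) {
  y <- results[[response]]
  mu <- ave(y, results$diet_name, FUN = mean)
  resid <- y - mu
  s <- sqrt(sum(resid^2) / max(1, length(y) - length(unique(results$diet_name))))
  z <- if (s > 0) resid / s else resid * 0
  out <- results[abs(z) > threshold, , drop = FALSE]
  out$z <- z[abs(z) > threshold]
  out
}
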