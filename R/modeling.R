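# Correlation screening and stepwise construction/application of DE/ME
# prediction equations.

#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson correlations over complete ingredient-level data, with
#' two-sided p-values from the t transform `t = r * sqrt((n-2)/(1-r^2))`
#' on n - 2 degrees of freedom.
#'
#' @param table data.frame of ingredient-level values (one row per
#'   ingredient), no missing values.
#' @param variables columns to correlate, in display order.
#' @return object of class `correlation_matrix`: list with `variables`,
#'   `r` (symmetric matrix, unit diagonal), `p` (p-value matrix, `NA`
#'   diagonal), `n`.
#' @export
pearson_matrix <- function(table, variables = names(table)) {
  stopifnot(is.data.frame(table), all(variables %in% names(table)))
  x <- as.matrix(table[variables])
  if (!is.numeric(x) || anyNA(x)) {
    fe_stop("pearson_matrix: variables must be numeric with no missing values",
            "feedenergy_invalid_input")
  }
  n <- nrow(x)
  if (n < 3L) {
    fe_stop("pearson_matrix needs n >= 3 rows", "feedenergy_insufficient_data")
  }
  degenerate <- apply(x, 2, stats::sd) == 0
  if (any(degenerate)) {
    fe_stop(sprintf("pearson_matrix: zero variance in %s",
                    paste(variables[degenerate], collapse = ", ")),
            "feedenergy_undefined_correlation")
  }
  r <- stats::cor(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  structure(list(variables = variables, r = r, p = p, n = n),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  # stars follow the reporting convention: ** p < 0.05, * 0.05 <= p < 0.10
  stars <- ifelse(is.na(x$p), "",
                  ifelse(x$p < 0.05, " **", ifelse(x$p < 0.10, " *", "")))
  cells <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), stars),
                  nrow = nrow(x$r), dimnames = dimnames(x$r))
  cells[upper.tri(cells)] <- ""
  cat(sprintf("Pearson correlations (n = %d); ** p < 0.05, * p < 0.10\n", x$n))
  print(as.data.frame(cells), right = TRUE)
  invisible(x)
}

#' Create a prediction equation
#'
#' A linear DE/ME prediction equation: intercept plus coefficients on
#' chemical analytes (%) and, for ME, possibly on DE (MJ/kg), all tied to a
#' declared basis.
#'
#' @param response `"DE"` or `"ME"`.
#' @param basis `"as_fed"` or `"dry_matter"`.
#' @param intercept MJ/kg.
#' @param coefficients named numeric vector. The canonical feed predictors
#'   `DM`, `ash`, `EE`, `NDF`, `ADF`, `CP`, `starch`, `GE`, `DE` map onto
#'   [nutrient_profile()] and [energy_result()] fields when the equation is
#'   applied; other names are allowed for generic regressions.
#' @param r2 coefficient of determination in \[0, 1\] (`NA` if unknown).
#' @param p_value overall model p-value (`NA` if unknown).
#' @return object of class `prediction_equation`.
#' @export
prediction_equation <- function(response, basis, intercept, coefficients,
                                r2 = NA_real_, p_value = NA_real_) {
  response <- match.arg(response, c("DE", "ME"))
  check_basis(basis)
  if (length(coefficients) && (is.null(names(coefficients)) ||
                               any(!nzchar(names(coefficients))))) {
    fe_stop("equation coefficients must all be named",
            "feedenergy_invalid_equation")
  }
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) {
    fe_stop("r2 must lie in [0, 1]", "feedenergy_invalid_equation")
  }
  structure(list(response = response, basis = basis,
                 intercept = as.numeric(intercept),
                 coefficients = coefficients, r2 = r2, p_value = p_value),
            class = "prediction_equation")
}

#' @export
print.prediction_equation <- function(x, ...) {
  terms <- if (length(x$coefficients)) {
    paste(sprintf("%+.4f x %s", x$coefficients, names(x$coefficients)),
          collapse = " ")
  } else ""
  cat(sprintf("%s (MJ/kg, %s) = %s %+.4f   [R2 = %s, p = %s]\n",
              x$response, sub("_", " ", x$basis), terms, x$intercept,
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2)),
              ifelse(is.na(x$p_value), "NA", format.pval(x$p_value, digits = 3))))
  invisible(x)
}

# map equation predictor names to profile / result fields
PREDICTOR_FIELDS <- c(DM = "dm_pct", ash = "ash_pct", EE = "ee_pct",
                      NDF = "ndf_pct", ADF = "adf_pct", CP = "cp_pct",
                      starch = "starch_pct", GE = "ge_mj_per_kg",
                      DE = "de_mj_per_kg")

#' Apply a prediction equation
#'
#' Evaluates `intercept + sum(coef * value)` on a nutrient profile, an
#' ingredient table row, or a named list/vector of predictor values. When
#' the input carries a basis it must match the equation's basis.
#'
#' @param eq a [prediction_equation()].
#' @param data a [nutrient_profile()], a data.frame (one value per row), or
#'   a named list/vector keyed by predictor name (`DM`, `ADF`, `starch`,
#'   `DE`, ...) or by the corresponding table column (`adf_pct`, ...).
#' @return predicted energy, MJ/kg on the equation's basis.
#' @examples
#' eq <- prediction_equation("DE", "as_fed", 11.4467,
#'                           c(starch = 0.1364, ADF = -0.2352))
#' apply_equation(eq, c(starch = 50, ADF = 10))
#' @export
apply_equation <- function(eq, data) {
  stopifnot(inherits(eq, "prediction_equation"))
  if (inherits(eq$basis, "character") &&
      (inherits(data, "nutrient_profile") ||
       (is.data.frame(data) && "basis" %in% names(data)))) {
    bas <- if (inherits(data, "nutrient_profile")) data$basis else
      unique(data$basis)
    if (!identical(bas, eq$basis)) {
      fe_stop(sprintf("equation is on %s basis but data are on %s",
                      eq$basis, paste(bas, collapse = "/")),
              "feedenergy_basis_error")
    }
  }
  lookup <- function(nm) {
    for (key in c(nm, unname(PREDICTOR_FIELDS[nm]))) {
      if (!is.null(key) && !is.na(key) && key %in% names(data)) {
        return(if (is.data.frame(data)) data[[key]] else data[[key]])
      }
    }
    fe_stop(sprintf("predictor '%s' missing from data", nm),
            "feedenergy_missing_predictor")
  }
  out <- eq$intercept
  for (nm in names(eq$coefficients)) {
    out <- out + eq$coefficients[[nm]] * lookup(nm)
  }
  unname(out)
}

#' Stepwise regression path
#'
#' Forward selection with replacement: at each step the candidate whose
#' partial F-test has the smallest p-value enters if p <= `sle`; after each
#' entry, included predictors with partial p > `sls` are removed (worst
#' first) until all stay; the procedure stops at a fixed point. Ties on the
#' entry p-value break lexicographically by predictor name. Candidates that
#' are collinear with the current model (no added rank) are skipped with a
#' warning. The fitted equation after every successful entry is emitted, so
#' the path contains one model per size reached.
#'
#' @param table data.frame of observations.
#' @param response response column name.
#' @param candidates candidate predictor column names.
#' @param sle significance level to enter (default 0.15).
#' @param sls significance level to stay (default 0.15).
#' @param basis basis label stored on the emitted equations.
#' @param predictor_names optional named character vector mapping column
#'   names to canonical predictor names (e.g. `c(adf_pct = "ADF")`).
#' @return object of class `stepwise_path`: list of
#'   [prediction_equation()]s in entry order (largest last), with the
#'   selected column names in `attr(, "selected")`.
#' @export
stepwise_fit <- function(table, response, candidates, sle = 0.15, sls = 0.15,
                         basis = "dry_matter", predictor_names = NULL) {
  stopifnot(is.data.frame(table), response %in% names(table),
            all(candidates %in% names(table)))
  n <- nrow(table)
  if (n < 3L) fe_stop("stepwise_fit: too few observations",
                      "feedenergy_insufficient_data")
  y <- table[[response]]
  candidates <- sort(candidates)   # lexicographic scan order; ties break here

  fit_model <- function(vars) {
    fml <- if (length(vars)) {
      stats::as.formula(paste(response, "~",
                              paste(sprintf("`%s`", vars), collapse = "+")))
    } else stats::as.formula(paste(response, "~ 1"))
    stats::lm(fml, data = table)
  }
  # partial F p-value for adding `var` to `vars`
  entry_p <- function(vars, var) {
    base <- fit_model(vars)
    full <- fit_model(c(vars, var))
    if (anyNA(coef(full))) return(NA_real_)   # collinear: no added rank
    an <- stats::anova(base, full)
    an[["Pr(>F)"]][2]
  }
  # partial p-values of each included predictor (drop-one F tests)
  stay_p <- function(vars) {
    full <- fit_model(vars)
    vapply(vars, function(v) {
      red <- fit_model(setdiff(vars, v))
      stats::anova(red, full)[["Pr(>F)"]][2]
    }, numeric(1))
  }

  selected <- character(0)
  path <- list()
  seen <- character(0)   # visited models, to guarantee termination
  repeat {
    if (n <= length(selected) + 2) break   # no residual df for a further entry
    pool <- setdiff(candidates, selected)
    if (!length(pool)) break
    ps <- vapply(pool, function(v) entry_p(selected, v), numeric(1))
    if (any(is.na(ps))) {
      warning(sprintf("skipping collinear candidate(s): %s",
                      paste(pool[is.na(ps)], collapse = ", ")))
      pool <- pool[!is.na(ps)]; ps <- ps[!is.na(ps)]
    }
    if (!length(ps) || min(ps) > sle) break
    selected <- c(selected, pool[which.min(ps)])   # first min = lexicographic
    repeat {
      sp <- stay_p(selected)
      if (max(sp) <= sls) break
      selected <- setdiff(selected, names(sp)[which.max(sp)])
      if (!length(selected)) break
    }
    key <- paste(sort(selected), collapse = "|")
    if (key %in% seen) break
    seen <- c(seen, key)
    fit <- fit_model(selected)
    sm <- summary(fit)
    pval <- if (length(selected)) {
      f <- sm$fstatistic
      stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
    } else NA_real_
    coefs <- coef(fit)[-1]
    names(coefs) <- canonical_predictor(names(coefs), predictor_names)
    path[[length(path) + 1]] <- prediction_equation(
      response = if (toupper(response) %in% c("DE", "ME")) toupper(response)
                 else if (grepl("^me", response)) "ME" else "DE",
      basis = basis, intercept = unname(coef(fit)[1]),
      coefficients = coefs, r2 = sm$r.squared, p_value = unname(pval))
  }
  structure(path, class = "stepwise_path", selected = selected)
}

canonical_predictor <- function(cols, predictor_names) {
  cols <- gsub("`", "", cols)
  out <- cols
  for (i in seq_along(cols)) {
    if (!is.null(predictor_names) && cols[i] %in% names(predictor_names)) {
      out[i] <- predictor_names[[cols[i]]]
    } else if (cols[i] %in% PREDICTOR_FIELDS) {
      out[i] <- names(PREDICTOR_FIELDS)[match(cols[i], PREDICTOR_FIELDS)]
    }
  }
  out
}

#' @export
print.stepwise_path <- function(x, ...) {
  cat(sprintf("Stepwise path (%d model%s):\n", length(x),
              if (length(x) == 1) "" else "s"))
  for (eq in x) print(eq)
  invisible(x)
}

#' Read / write an equation registry
#'
#' Plain-text key-value format, one equation per block separated by blank
#' lines: `response:`, `basis:`, `intercept:`, `coef.<name>:`, `r2:`, `p:`.
#' Numbers round-trip at full double precision (17 significant digits).
#'
#' @param path file path.
#' @return `read_equation_registry()`: list of [prediction_equation()]s.
#' @export
read_equation_registry <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  blocks <- Filter(function(b) any(nzchar(trimws(b))), blocks)
  lapply(blocks, function(b) {
    b <- b[nzchar(trimws(b))]
    kv <- strsplit(b, ":", fixed = TRUE)
    keys <- trimws(vapply(kv, `[[`, "", 1))
    vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
    named <- setNames(vals, keys)
    is_coef <- startsWith(keys, "coef.")
    coefs <- as.numeric(vals[is_coef])
    names(coefs) <- sub("^coef\\.", "", keys[is_coef])
    prediction_equation(
      response = named[["response"]], basis = named[["basis"]],
      intercept = as.numeric(named[["intercept"]]), coefficients = coefs,
      r2 = if ("r2" %in% keys) as.numeric(named[["r2"]]) else NA_real_,
      p_value = if ("p" %in% keys) as.numeric(named[["p"]]) else NA_real_)
  })
}

#' @rdname read_equation_registry
#' @param equations list of [prediction_equation()]s.
#' @return `write_equation_registry()`: `path`, invisibly.
#' @export
write_equation_registry <- function(equations, path) {
  if (inherits(equations, "prediction_equation")) equations <- list(equations)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  blocks <- vapply(equations, function(eq) {
    lines <- c(paste0("response: ", eq$response),
               paste0("basis: ", eq$basis),
               paste0("intercept: ", fmt(eq$intercept)),
               sprintf("coef.%s: %s", names(eq$coefficients),
                       fmt(unlist(eq$coefficients))),
               paste0("r2: ", fmt(eq$r2)),
               paste0("p: ", fmt(eq$p_value)))
    paste(lines, collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Published reference prediction equations
#'
#' The four DE/ME prediction equations shipped with the package (as-fed
#' basis): a one- and a two-predictor DE equation on fiber and starch, and
#' ME equations on DE with and without a crude-protein term. Loaded from
#' the plain-text registry under `inst/extdata`.
#'
#' @return list of four [prediction_equation()]s.
#' @examples
#' eqs <- reference_equations()
#' apply_equation(eqs[[2]], c(starch = 50, ADF = 10))
#' @export
reference_equations <- function() {
  read_equation_registry(system.file("extdata", "equations_registry.txt",
                                     package = "feedenergy", mustWork = TRUE))
}
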