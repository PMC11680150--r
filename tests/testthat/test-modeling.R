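test_that("pearson matrix matches cor.test pair by pair", {
  set.seed(21)
  tab <- data.frame(a = rnorm(15), b = rnorm(15), c = rnorm(15))
  tab$b <- tab$b + 0.8 * tab$a
  cm <- pearson_matrix(tab)
  expect_equal(diag(cm$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    ct <- cor.test(tab[[pair[1]]], tab[[pair[2]]])
    expect_equal(cm$r[pair[1], pair[2]], unname(ct$estimate),
                 tolerance = 1e-12)
    expect_equal(cm$p[pair[1], pair[2]], ct$p.value, tolerance = 1e-9)
  }
})

test_that("exact linear relations give r of +/- 1", {
  x <- c(1, 3, 4, 7, 9)
  cm <- pearson_matrix(data.frame(x = x, y = 2 * x, z = -x))
  expect_equal(cm$r["x", "y"], 1, tolerance = 1e-12)
  expect_equal(cm$r["x", "z"], -1, tolerance = 1e-12)
  expect_lt(cm$p["x", "y"], 1e-10)

  expect_error(pearson_matrix(data.frame(x = x, k = rep(2, 5))),
               class = "feedenergy_undefined_correlation")
})

test_that("published ingredient DE and ME means are almost collinear", {
  t5 <- reference_ingredient_results()
  panel <- cereal_panel()
  vals <- ingredient_value_table(t5, panel, basis = "dry_matter")
  cm <- pearson_matrix(vals, c("DE", "ME"))
  expect_gte(cm$r["DE", "ME"], 0.99)
})

test_that("stepwise recovers a noiseless linear law exactly", {
  x <- seq(1, 20)
  tab <- data.frame(x = x, y = 2 + 3 * x)
  path <- suppressWarnings(stepwise_fit(tab, "y", "x", basis = "as_fed"))
  eq <- path[[length(path)]]
  expect_equal(eq$intercept, 2, tolerance = 1e-9)
  expect_equal(unname(eq$coefficients[["x"]]), 3, tolerance = 1e-9)
  expect_equal(eq$r2, 1, tolerance = 1e-12)
})

test_that("stepwise selects the generating analytes and their coefficients", {
  set.seed(42)
  n <- 200
  tab <- data.frame(starch = runif(n, 35, 72), ADF = runif(n, 1.5, 15))
  tab$DE <- 0.14 * tab$starch - 0.24 * tab$ADF + 11 + rnorm(n, sd = 0.05)
  path <- stepwise_fit(tab, "DE", c("ADF", "starch"), basis = "as_fed")
  expect_setequal(attr(path, "selected"), c("starch", "ADF"))
  eq <- path[[length(path)]]
  expect_equal(unname(eq$coefficients[["starch"]]), 0.14, tolerance = 0.05)
  expect_equal(unname(eq$coefficients[["ADF"]]), -0.24, tolerance = 0.05)
})

test_that("stepwise path R-squared is monotone and collinear candidates are skipped", {
  set.seed(23)
  n <- 60
  tab <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  tab$dup <- 2 * tab$a                     # exactly collinear with a
  tab$y <- tab$a + 0.5 * tab$b + rnorm(n, sd = 0.3)
  ws <- capture_warnings(path <- stepwise_fit(tab, "y", c("a", "b", "c", "dup")))
  expect_true(any(grepl("collinear", ws)))
  r2 <- vapply(path, `[[`, numeric(1), "r2")
  expect_true(all(diff(r2) >= -1e-12))
  expect_false("dup" %in% attr(path, "selected"))
})

test_that("stepwise models match the exhaustive best subset almost always", {
  set.seed(24)
  n <- 40; p <- 6
  match_count <- 0; comparisons <- 0
  for (rep in 1:100) {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("v", 1:p)))
    beta <- c(1.2, -0.8, 0.5, 0, 0, 0)[sample(p)]
    tab <- as.data.frame(X)
    tab$y <- drop(X %*% beta) + rnorm(n, sd = 0.6)
    path <- stepwise_fit(tab, "y", colnames(X))
    for (eq in path) {
      k <- length(eq$coefficients)
      best <- max(vapply(utils::combn(colnames(X), k, simplify = FALSE),
                         function(vars) {
                           summary(lm(stats::reformulate(vars, "y"),
                                      data = tab))$r.squared
                         }, numeric(1)))
      expect_lte(eq$r2, best + 1e-10)   # never beats the exhaustive best
      comparisons <- comparisons + 1
      if (abs(eq$r2 - best) < 1e-10) match_count <- match_count + 1
    }
  }
  expect_gte(match_count / comparisons, 0.9)
})

test_that("equations apply linearly and guard basis and predictors", {
  eqs <- reference_equations()
  expect_length(eqs, 4)
  expect_equal(apply_equation(eqs[[1]], c(ADF = 0)), 14.3722)
  expect_equal(apply_equation(eqs[[2]], c(starch = 50, ADF = 10)),
               0.1364 * 50 - 0.2352 * 10 + 11.4467, tolerance = 1e-12)
  expect_equal(apply_equation(eqs[[4]], c(DE = 14, CP = 10)),
               0.9838 * 14 - 0.0165 * 10 + 0.0538, tolerance = 1e-12)

  # doubling coefficients and intercept doubles the output
  eq <- eqs[[2]]
  doubled <- prediction_equation(eq$response, eq$basis, 2 * eq$intercept,
                                 2 * eq$coefficients)
  x <- c(starch = 61.3, ADF = 4.2)
  expect_equal(apply_equation(doubled, x), 2 * apply_equation(eq, x),
               tolerance = 1e-12)

  # as-fed equation refuses a dry-matter profile
  prof <- random_profile()
  expect_error(apply_equation(eqs[[1]], prof),
               class = "feedenergy_basis_error")
  expect_error(apply_equation(eqs[[2]], c(starch = 50)),
               class = "feedenergy_missing_predictor")
})

test_that("the equation registry round-trips bit exactly", {
  eqs <- reference_equations()
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_equation_registry(eqs, tmp)
  back <- read_equation_registry(tmp)
  expect_length(back, length(eqs))
  for (i in seq_along(eqs)) {
    expect_identical(back[[i]]$intercept, eqs[[i]]$intercept)
    expect_identical(unlist(back[[i]]$coefficients),
                     unlist(eqs[[i]]$coefficients))
    expect_identical(back[[i]]$r2, eqs[[i]]$r2)
    expect_identical(back[[i]]$response, eqs[[i]]$response)
    expect_identical(back[[i]]$basis, eqs[[i]]$basis)
  }
})
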