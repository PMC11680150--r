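test_that("complete balanced layouts give raw diet means", {
  set.seed(11)
  grid <- expand.grid(pig_id = 1:4, period = 1:4)
  grid$diet_name <- LETTERS[((grid$pig_id + grid$period - 2) %% 4) + 1]
  grid$y <- rnorm(nrow(grid), mean = match(grid$diet_name, LETTERS))
  ls <- diet_lsmeans(grid, "y")
  raw <- tapply(grid$y, grid$diet_name, mean)
  expect_equal(ls$table$lsmean, as.vector(raw[ls$table$name]),
               tolerance = 1e-10)
})

test_that("adding a constant shifts every lsmean, leaving SEM unchanged", {
  set.seed(12)
  d <- youden_design(7, 4)
  d$y <- rnorm(nrow(d)) + match(d$diet_name, unique(d$diet_name))
  ls0 <- diet_lsmeans(d, "y")
  d$y <- d$y + 3.5
  ls1 <- diet_lsmeans(d, "y")
  expect_equal(ls1$table$lsmean, ls0$table$lsmean + 3.5, tolerance = 1e-10)
  expect_equal(ls1$sem, ls0$sem, tolerance = 1e-12)
  expect_equal(ls1$p_value, ls0$p_value, tolerance = 1e-10)
})

test_that("lsmeans agree with a hand-rolled normal-equations solve", {
  set.seed(13)
  d <- youden_design(6, 4)
  d$y <- rnorm(nrow(d), sd = 0.4) +
    match(d$diet_name, unique(d$diet_name)) * 0.7 +
    c(0.5, -0.5, 0.2, -0.2)[d$period]
  ls <- diet_lsmeans(d, "y")

  # oracle: explicit least squares + uniform averaging over periods
  X <- stats::model.matrix(~ factor(diet_name) + factor(period), data = d)
  beta <- solve(crossprod(X), crossprod(X, d$y))
  diets <- sort(unique(d$diet_name))
  periods <- sort(unique(d$period))
  oracle <- vapply(diets, function(dn) {
    mean(vapply(periods, function(pp) {
      x <- X[1, ]; x[] <- 0; x["(Intercept)"] <- 1
      dcol <- paste0("factor(diet_name)", dn)
      pcol <- paste0("factor(period)", pp)
      if (dcol %in% names(x)) x[dcol] <- 1
      if (pcol %in% names(x)) x[pcol] <- 1
      sum(x * beta)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(ls$table$lsmean[match(diets, ls$table$name)], unname(oracle),
               tolerance = 1e-8)
})

test_that("a known diet shift is recovered exactly without noise", {
  d <- expand.grid(pig_id = 1:2, period = 1:2)
  d$diet_name <- ifelse((d$pig_id + d$period) %% 2 == 0, "A", "B")
  d$y <- ifelse(d$diet_name == "B", 2.0, 1.0) + 0.3 * d$period
  ls <- suppressWarnings(diet_lsmeans(d, "y"))
  tab <- setNames(ls$table$lsmean, ls$table$name)
  expect_equal(unname(tab["B"] - tab["A"]), 1.0, tolerance = 1e-10)
})

test_that("period-adjusted means cover the truth at the nominal rate", {
  # 13 x 6 Youden rows with +/-0.5 period effects; 2*SE is a ~95% interval
  # (t with 60 df), so pooled coverage over 200 seeds should not fall
  # meaningfully below nominal; 0.93 allows 3 SD of binomial fluctuation
  truth <- seq(14, 17, length.out = 13)
  design <- youden_design(13, 6)
  hits <- total <- 0
  for (seed in 1:200) {
    set.seed(seed)
    period_eff <- runif(6, -0.5, 0.5)
    d <- design
    d$y <- truth[match(d$diet_name, unique(design$diet_name))] +
      period_eff[d$period] + rnorm(nrow(d), sd = 0.2)
    ls <- diet_lsmeans(d, "y")
    est <- ls$table$lsmean[match(unique(design$diet_name), ls$table$name)]
    se <- ls$table$se[match(unique(design$diet_name), ls$table$name)]
    # period effects shift all diets equally: compare centred values
    dev <- (est - mean(est)) - (truth - mean(truth))
    hits <- hits + sum(abs(dev) <= 2 * se)
    total <- total + length(dev)
  }
  expect_gt(hits / total, 0.93)
})

test_that("disconnected assignments and degenerate inputs error", {
  d <- data.frame(pig_id = c(1, 1, 2, 2), period = c(1, 2, 1, 2),
                  diet_name = "only", y = rnorm(4))
  expect_error(diet_lsmeans(d, "y"), class = "feedenergy_invalid_design")
})

test_that("the design validator enforces the Youden structure", {
  good <- youden_design(5, 3)
  expect_silent(validate_design(good))
  bad <- good
  bad$diet_name[1] <- bad$diet_name[2]   # duplicates within a period
  expect_error(validate_design(bad), class = "feedenergy_invalid_design")
})
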