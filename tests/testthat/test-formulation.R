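test_that("formulation specs validate inclusion closure and naming", {
  expect_error(formulation_spec("d", c(a = 50, b = 49), "a"),
               class = "feedenergy_invalid_formulation")
  expect_error(formulation_spec("d", c(a = 50, b = 50), "c"),
               class = "feedenergy_invalid_formulation")
  expect_error(formulation_spec("d", setNames(c(50, 50), c("a", "")), "a"),
               class = "feedenergy_invalid_formulation")
})

test_that("expected diet profile is the inclusion-weighted as-fed mixture", {
  a <- nutrient_profile("A", "as_fed", 88, 1.5, 3, 10, 3, 8, 55, 18.0)
  panel <- as.data.frame(a)
  diet <- formulation_spec("d", c(A = 97.4, inert = 2.6), "A")
  prof <- expected_diet_profile(diet, panel)
  expect_equal(prof$ge_mj_per_kg, 0.974 * 18.0, tolerance = 1e-12)
  expect_identical(prof$basis, "as_fed")

  # 100% single-ingredient diet reproduces the ingredient
  solo <- expected_diet_profile(formulation_spec("solo", c(A = 100), "A"),
                                panel)
  for (f in c("dm_pct", "ge_mj_per_kg", "cp_pct", "starch_pct")) {
    expect_equal(solo[[f]], a[[f]], tolerance = 1e-12)
  }

  expect_error(
    expected_diet_profile(formulation_spec("d", c(B = 100), "B"), panel),
    class = "feedenergy_unknown_ingredient")
})

test_that("replacement test diet gross energy matches hand mixing of the panel", {
  prof <- expected_diet_profile(example_formulations()[["rice 5 diet"]],
                                cereal_panel())
  # 0.5844 * (18.58 * 0.8658) + 0.3896 * (17.84 * 0.8885)
  expect_equal(prof$ge_mj_per_kg, 15.57648, tolerance = 1e-4)
})

test_that("profile mixing is linear and order invariant", {
  set.seed(31)
  panel <- do.call(rbind, lapply(c("A", "B", "C"), function(nm)
    as.data.frame(random_profile(nm))))
  incl <- c(A = 40, B = 35, C = 22.4, filler = 2.6)
  d1 <- expected_diet_profile(formulation_spec("d", incl, c("A", "B", "C")),
                              panel)
  d2 <- expected_diet_profile(
    formulation_spec("d", incl[c(4, 2, 1, 3)], c("C", "A", "B")), panel)
  expect_equal(as.data.frame(d1), as.data.frame(d2), tolerance = 1e-12)
})

test_that("direct inclusion fraction sums energy-bearing inclusions", {
  forms <- example_formulations()
  for (dn in names(forms)) {
    expect_equal(direct_inclusion_fraction(forms[[dn]]), 0.974,
                 tolerance = 1e-12)
  }
  solo <- formulation_spec("s", c(A = 100), "A")
  expect_equal(direct_inclusion_fraction(solo), 1.0)
})

test_that("difference designs carry the exact replacement geometry", {
  ds <- difference_design("rice 5", "corn 5", "corn 5 diet", "rice 5 diet")
  expect_identical(ds$test_fraction, 0.974 * 0.40)
  expect_identical(ds$basal_fraction, 0.974 * 0.60)
  expect_equal(ds$test_fraction, 0.3896, tolerance = 1e-12)
  expect_error(difference_design("a", "b", "bd", "td",
                                 replacement_fraction = 1.2),
               class = "feedenergy_invalid_design")
})
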