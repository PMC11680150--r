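test_that("diet-level DE/ME follow the balance identities", {
  r <- make_record(fi = 5, ge_i = 90, ge_f = 9, ge_u = 1.8)
  er <- diet_energy(r)
  expect_equal(er$de_mj_per_kg, 16.2)
  expect_equal(er$me_mj_per_kg, 15.84)
  expect_equal(er$me_de_ratio_pct, 100 * 15.84 / 16.2)
  expect_false(er$flag_me_exceeds_de)

  # lossless limit: no fecal or urinary energy
  lossless <- diet_energy(make_record(ge_f = 0, ge_u = 0))
  expect_equal(lossless$de_mj_per_kg, lossless$me_mj_per_kg)
  expect_equal(lossless$me_de_ratio_pct, 100)

  expect_error(diet_energy(make_record(fi = 0)),
               class = "feedenergy_division_error")
})

test_that("direct method divides diet energy by the inclusion fraction", {
  er <- energy_result("diet", "corn 1 diet", "as_fed", 14.45, 14.17)
  ing <- ingredient_energy_direct(er, 0.974, "corn 1")
  expect_equal(round_half_up(ing$de_mj_per_kg, 2), 14.84)
  expect_equal(ing$me_de_ratio_pct, er$me_de_ratio_pct, tolerance = 1e-12)
  expect_identical(ing$level, "ingredient")

  expect_equal(ingredient_energy_direct(er, 1)$de_mj_per_kg, er$de_mj_per_kg)
  expect_error(ingredient_energy_direct(er, 0),
               class = "feedenergy_invalid_design")
})

test_that("published diet and ingredient as-fed tables reconcile through /0.974", {
  t4 <- reference_diet_results()
  t5 <- reference_ingredient_results()
  de_pairs <- c("corn 1", "corn 3", "corn 4", "corn 5", "wheat 2",
                "rice 1", "rice 2", "rice 3", "rice 4")
  for (nm in de_pairs) {
    diet_val <- reference_value(t4, "de_mj_per_kg", "as_fed",
                                paste(nm, "diet"))
    ing_val <- reference_value(t5, "de_mj_per_kg", "as_fed", nm)
    expect_equal(round_half_up(diet_val / 0.974, 2), ing_val,
                 info = paste("DE", nm))
  }
  me5 <- reference_value(t4, "me_mj_per_kg", "as_fed", "corn 5 diet")
  expect_equal(round_half_up(me5 / 0.974, 2),
               reference_value(t5, "me_mj_per_kg", "as_fed", "corn 5"))
})

test_that("difference method inverts the replacement mixture", {
  ds <- difference_design("test", "basal", "bd", "td")

  # substitution formula on inclusion-corrected diet values:
  # DE_d = 15.0, DE_c5 = 16.0 -> (15.0 - 16.0 * 0.6) / 0.3896
  test_diet <- energy_result("diet", "td", "as_fed", 15.0 * 0.974, 14.5 * 0.974)
  basal_diet <- energy_result("diet", "bd", "as_fed", 16.0 * 0.974, 15.5 * 0.974)
  est <- ingredient_energy_difference(test_diet, ds, mode = "as_printed",
                                      basal_reference = basal_diet)
  expect_equal(est$de_mj_per_kg, (15.0 - 9.6) / 0.3896, tolerance = 1e-12)

  # contribution mode: replacing an ingredient by itself returns it
  basal_ing <- energy_result("ingredient", "basal", "as_fed", 16.0, 15.5)
  self_diet <- energy_result("diet", "td", "as_fed", 0.974 * 16.0, 0.974 * 15.5)
  self <- ingredient_energy_difference(self_diet, ds, mode = "contribution",
                                       basal_reference = basal_ing)
  expect_equal(self$de_mj_per_kg, 16.0, tolerance = 1e-12)
  expect_equal(self$me_mj_per_kg, 15.5, tolerance = 1e-12)

  # basis mismatch between reference and test diet fails loudly
  basal_dm <- energy_result("ingredient", "basal", "dry_matter", 16, 15.5)
  expect_error(ingredient_energy_difference(self_diet, ds, "contribution",
                                            basal_dm),
               class = "feedenergy_basis_error")
})

test_that("basis conversion commutes with the inclusion correction", {
  er <- energy_result("diet", "d", "dry_matter", 15.9, 15.5, dm_pct = 88.4)
  a <- ingredient_energy_direct(convert_basis(er, "as_fed"), 0.974)
  b <- convert_basis(ingredient_energy_direct(er, 0.974, dm_pct = 88.4),
                     "as_fed")
  expect_equal(a$de_mj_per_kg, b$de_mj_per_kg, tolerance = 1e-12)
  expect_equal(a$me_mj_per_kg, b$me_mj_per_kg, tolerance = 1e-12)
})

test_that("diet ATTD follows the nutrient balance formula", {
  r <- make_record(fi = 5, fo = 0.8, dietconc_CP_pct = 10,
                   fecesconc_CP_pct = 25)
  att <- diet_attd(r, "CP")
  expect_equal(att$attd_pct, 60)

  # complete digestion limit
  r0 <- make_record(fi = 5, fo = 0, dietconc_CP_pct = 10,
                    fecesconc_CP_pct = 0)
  expect_equal(diet_attd(r0, "CP")$attd_pct, 100)

  # DM route uses the mass columns, GE route the energy columns
  expect_equal(diet_attd(make_record(fi = 5, fo = 0.6), "DM")$attd_pct, 88)
  expect_equal(diet_attd(make_record(ge_i = 90, ge_f = 9), "GE")$attd_pct, 90)

  bad <- make_record(dietconc_CP_pct = 0, fecesconc_CP_pct = 1)
  expect_error(diet_attd(bad, "CP"),
               class = "feedenergy_undefined_digestibility")
})

test_that("difference-method ATTD solves the contribution identity", {
  diet <- data.frame(level = "diet", name = "td", nutrient = "CP",
                     attd_pct = 75, pig_id = 1, period = 1,
                     stringsAsFactors = FALSE)
  est <- ingredient_attd_difference(diet, basal_ingredient_attd = 90,
                                    test_share = 0.4)
  expect_equal(est$attd_pct, (75 - 0.6 * 90) / 0.4)  # 52.5
  expect_false(est$flag_out_of_range)

  # homogeneous case: everything digests alike
  hom <- diet; hom$attd_pct <- 80
  expect_equal(ingredient_attd_difference(hom, 80, 0.37)$attd_pct, 80)

  # out-of-range estimates are flagged, not suppressed
  low <- diet; low$attd_pct <- 40
  flagged <- ingredient_attd_difference(low, 90, 0.3)
  expect_true(flagged$flag_out_of_range)
})

test_that("validation flags physically impossible records without dropping", {
  recs <- rbind(make_record(ge_i = 90, ge_f = 80, ge_u = 15),  # losses > intake
                make_record(pig_id = 2, ge_f = -1),
                make_record(pig_id = 3))
  v <- validate_balance(recs)
  expect_identical(nrow(v), 3L)
  expect_true(v$flag_energy_balance[1])
  expect_true(v$flag_negative_value[2])
  expect_false(any(unlist(v[3, c("flag_energy_balance", "flag_negative_value",
                                 "flag_nonpositive_intake")])))
  expect_identical(attr(v, "n_flagged"), 2L)
})
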