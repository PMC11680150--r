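test_that("the cyclic construction yields proper Youden rectangles", {
  d <- youden_design(13, 6)
  expect_identical(nrow(d), 78L)
  expect_true(all(table(d$diet_name) == 6))
  expect_true(all(table(d$diet_name, d$period) == 1))
  expect_true(all(table(d$diet_name, d$pig_id) <= 1))

  # complete-design limit: a Latin square
  sq <- youden_design(5, 5)
  expect_true(all(table(sq$diet_name, sq$pig_id) == 1))
  expect_true(all(table(sq$diet_name, sq$period) == 1))

  d53 <- youden_design(5, 3)
  expect_true(all(table(d53$diet_name) == 3))
  expect_true(all(table(d53$diet_name, d53$period) == 1))

  expect_error(youden_design(4, 6), class = "feedenergy_invalid_design")
})

test_that("the validator accepts every generated design", {
  for (t in c(3, 7, 13, 30)) {
    for (p in unique(c(2, ceiling(t / 2), t))) {
      expect_silent(validate_design(youden_design(t, p)))
    }
  }
})

test_that("true parameters enforce the energy ordering", {
  prof <- nutrient_profile("x", "dry_matter", 88, 2, 3, 12, 3, 9, 60, 18.4)
  expect_error(
    true_ingredient_params(prof, 19.0, 15.0, c(DM = 0.9)),  # DE > GE
    class = "feedenergy_invalid_params")
  expect_error(
    true_ingredient_params(prof, 15.0, 15.5, c(DM = 0.9)),  # ME > DE
    class = "feedenergy_invalid_params")
  expect_error(
    true_ingredient_params(prof, 16.0, 15.5, c(DM = 1.2)),
    class = "feedenergy_invalid_params")
  expect_s3_class(true_ingredient_params(prof, 16.0, 15.5, c(DM = 0.9)),
                  "true_ingredient_params")
})

test_that("a noiseless trial reproduces all diet-level truths exactly", {
  rec <- simulate_study(noise_model(0, 0, 0, 0, seed = 5))
  dt <- attr(rec, "diet_truth")
  den <- diet_energy(rec)
  for (dn in dt$diet_name) {
    expect_equal(unique(den$de_mj_per_kg[den$name == dn]),
                 dt$true_de_dm[dt$diet_name == dn], tolerance = 1e-12)
    expect_equal(unique(den$me_mj_per_kg[den$name == dn]),
                 dt$true_me_dm[dt$diet_name == dn], tolerance = 1e-12)
  }
  for (nu in c("DM", "CP", "NDF", "ADF", "ash", "EE")) {
    att <- diet_attd(rec, nu)
    for (dn in dt$diet_name) {
      expect_equal(unique(round(att$attd_pct[att$name == dn], 9)),
                   100 * dt[[paste0("true_attd_", nu)]][dt$diet_name == dn],
                   tolerance = 1e-8)
    }
  }
})

test_that("same seed gives identical records; noise respects energy balance", {
  a <- simulate_study(noise_model(seed = 77))
  b <- simulate_study(noise_model(seed = 77))
  expect_identical(a, b)
  c <- simulate_study(noise_model(seed = 78))
  expect_false(identical(a, c))
  expect_true(all(a$ge_feces_mj + a$ge_urine_mj <= a$ge_intake_mj))
  expect_true(all(a$feed_intake_kg_dm > 0))
})

test_that("feed offer follows the body-weight rule", {
  rec <- simulate_study(noise_model(0, 0, 0, 0, seed = 5))
  dt <- attr(rec, "diet_truth")
  r1 <- rec[1, ]
  dm <- dt$dm_pct[dt$diet_name == r1$diet_name] / 100
  expect_equal(r1$feed_intake_kg_dm, 0.04 * 45.32 * 5 * dm, tolerance = 1e-12)
})

test_that("the difference method recovers a replaced ingredient at zero noise", {
  rec <- simulate_study(noise_model(0, 0, 0, 0, seed = 9))
  ev <- evaluate_study(rec)
  truth <- attr(rec, "truth")
  s <- ev$ingredient_summary
  for (nm in c("rice 5", "rice 6")) {
    expect_equal(summary_row(s, "de_mj_per_kg", "dry_matter", nm),
                 truth$true_de[truth$ingredient == nm],
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(summary_row(s, "attd_CP", "dry_matter", nm),
                 100 * truth$true_attd_CP[truth$ingredient == nm],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})
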