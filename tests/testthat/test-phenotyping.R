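test_that("hypertension classification follows the JNC-7 thresholds", {
  expect_true(classify_hypertension(140, 85, FALSE))
  expect_true(classify_hypertension(120, 90, FALSE))
  expect_true(classify_hypertension(120, 75, TRUE))
  expect_false(classify_hypertension(139, 89, FALSE))
  # undecided: observed criteria negative, another missing
  expect_true(is.na(classify_hypertension(120, NA, FALSE)))
  # decided positive even with a missing companion
  expect_true(classify_hypertension(150, NA, NA))
  expect_error(classify_hypertension(-1, 80, FALSE),
               class = "mds_validation_error")
})

test_that("diabetes classification follows the WHO criteria", {
  expect_true(classify_diabetes(7.0, NA, FALSE, FALSE))
  expect_true(classify_diabetes(5.0, 11.1, FALSE, FALSE))
  expect_true(classify_diabetes(NA, NA, TRUE, FALSE))
  expect_false(classify_diabetes(5.0, 6.0, FALSE, FALSE))
  expect_true(is.na(classify_diabetes(5.0, NA, FALSE, FALSE)))
})

test_that("eGFR matches the CKD-EPI 2009 equation without race coefficient", {
  expect_equal(egfr_ckd_epi(0.8, 50, "Female"), 86.0, tolerance = 5e-4)
  # at Scr = kappa both spline terms are 1; age term -> 1 as age -> 0
  expect_equal(egfr_ckd_epi(0.9, 1e-9, "Male"), 141, tolerance = 1e-6)
  # umol/L inputs are divided by 88.4
  expect_equal(egfr_ckd_epi(0.8 * 88.4, 50, "Female", unit = "umol/L"),
               egfr_ckd_epi(0.8, 50, "Female"))
  expect_error(egfr_ckd_epi(0, 50, "Female"), class = "mds_validation_error")
})

test_that("CKD requires low eGFR (inclusive) or albuminuria (exclusive)", {
  expect_true(classify_ckd(60.0, 1.0))
  expect_false(classify_ckd(90.0, 3.0))
  expect_true(classify_ckd(90.0, 3.1))
  expect_true(is.na(classify_ckd(NA, NA)))
})

test_that("CVD is any positive self-report, including CHF and angina", {
  expect_true(classify_cvd(FALSE, TRUE, FALSE, FALSE))
  expect_true(classify_cvd(FALSE, FALSE, FALSE, TRUE))
  expect_false(classify_cvd(FALSE, FALSE, FALSE, FALSE))
  expect_true(is.na(classify_cvd(NA, NA, NA, NA)))
})

test_that("multimorbidity is >= 2 of the 4 conditions", {
  expect_true(derive_multimorbidity(TRUE, TRUE, FALSE, FALSE))
  expect_false(derive_multimorbidity(TRUE, FALSE, FALSE, FALSE))
  expect_true(derive_multimorbidity(TRUE, TRUE, TRUE, TRUE))
  expect_true(is.na(derive_multimorbidity(TRUE, NA, FALSE, FALSE)))
})

test_that("inclusion keeps ages 40-60 with derivable flags", {
  raw <- raw_cohort(raw_row(), raw_row(age = 39), raw_row(age = 61),
                    raw_row(age = 40), raw_row(age = 60),
                    raw_row(creatinine = NA, uacr = NA),
                    raw_row(sbp = 150), raw_row(fasting_glucose = 8),
                    raw_row(angina = TRUE), raw_row(uacr = 5))
  ph <- phenotype_cohort(raw)
  expect_equal(nrow(ph), 7)      # 2 out of age range, 1 underivable CKD
  expect_equal(attr(ph, "mu"), mean(ph$mm))
  expect_equal(attr(ph, "n_raw"), 10)
  # all-eligible cohort passes through unchanged
  raw2 <- raw_cohort(raw_row(), raw_row(sbp = 160, uacr = 9))
  expect_equal(nrow(phenotype_cohort(raw2)), 2)
  expect_true(phenotype_cohort(raw2)$mm[2])
})

test_that("retention is near 94% when missingness is tuned to match", {
  sp <- cohort_spec("a", 4000, 0.164, missing_rate = 0.005, seed = 21)
  ph <- phenotype_cohort(generate_cohort(sp, mode = "biomarker"))
  expect_gt(attr(ph, "retention"), 0.90)
  expect_lt(attr(ph, "retention"), 0.97)
})

test_that("raising the SBP threshold can never increase HT prevalence", {
  set.seed(2)
  sbp <- runif(500, 90, 200); dbp <- runif(500, 60, 120)
  meds <- runif(500) < 0.2
  prev <- vapply(c(120, 140, 160), function(th)
    mean(or3(sbp >= th, dbp >= 90, meds) %in% TRUE), 0)
  expect_true(all(diff(prev) <= 0))
})

test_that("co-occurrence counts partition the multimorbid-or-single set", {
  toy <- data.frame(ht = c(TRUE, TRUE, FALSE, FALSE),
                    dm = c(FALSE, FALSE, FALSE, TRUE),
                    ckd = c(FALSE, TRUE, FALSE, FALSE),
                    cvd = FALSE)
  cc <- cooccurrence_counts(toy)
  expect_equal(unname(cc["HT"]), 1L)
  expect_equal(unname(cc["HT+CKD"]), 1L)
  expect_equal(unname(cc["DM"]), 1L)
  expect_equal(sum(cc), 3L)
  # property: counts always sum to the number with >= 1 condition
  sp <- cohort_spec("a", 800, 0.15, missing_rate = 0, seed = 4)
  ph <- phenotype_cohort(generate_cohort(sp, mode = "biomarker"))
  expect_equal(sum(cooccurrence_counts(ph)),
               sum(ph$ht | ph$dm | ph$ckd | ph$cvd))
})
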