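test_that("Woolf interval reproduces the published reconstruction", {
  ci <- or_ci(c(33, 86, 139, 1519))
  expect_equal(ci$or, 4.193, tolerance = 1e-3)
  expect_equal(ci$ci_low, 2.71, tolerance = 0.002)
  expect_equal(ci$ci_high, 6.49, tolerance = 0.002)
})

test_that("Woolf interval behaves under symmetry and doubling", {
  ci <- or_ci(c(25, 40, 25, 40))
  expect_equal(ci$or, 1)
  expect_lt(ci$ci_low, 1); expect_gt(ci$ci_high, 1)
  c1 <- or_ci(c(20, 30, 15, 60))
  c2 <- or_ci(2 * c(20, 30, 15, 60))
  expect_equal(c1$or, c2$or)
  expect_lt(c2$ci_high - c2$ci_low, c1$ci_high - c1$ci_low)
  # zero cell: corrected and flagged
  cz <- or_ci(c(0, 30, 15, 60))
  expect_true(cz$haldane)
  expect_false(is.na(cz$or))
})

test_that("identity transfer reproduces the source mask and stats", {
  truth <- mds_description(mds_literal("age", ">=", 52))
  co <- generate_cohort(cohort_spec("a", 900, 0.2, missing_rate = 0, seed = 6),
                        list(planted_signal(truth, 4)), mode = "outcome")
  fit <- mdscan(mm ~ age + sex + bmi, co, rho = 1, restarts = 3, seed = 2)
  tr <- mdscan_transfer(fit, co)
  expect_identical(predict(fit, co), subset_mask(co, fit$description))
  expect_equal(tr$stats$a, fit$stats$a)
  expect_equal(tr$or, fit$stats$or)
  expect_true(tr$ci_low <= tr$or && tr$or <= tr$ci_high)
})

test_that("descriptions evaluate on a hand-written target by enumeration", {
  desc <- mds_description(mds_literal("age", ">=", 53),
                          mds_literal("waist_circumference", ">=", 950))
  target <- data.frame(age = c(55, 52, 60, 53, NA),
                       waist_circumference = c(960, 990, 940, 950, 970),
                       mm = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  m <- subset_mask(target, desc)
  expect_identical(m, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  # a missing referenced column fails naming the feature
  expect_error(mdscan_transfer(desc, target[, c("age", "mm")]),
               "waist_circumference")
})

test_that("transfer of a strong planted subset is robust; null transfer is not", {
  desc <- mds_description(mds_literal("sex", "in", "Female"),
                          mds_literal("age", ">=", 54))
  source <- generate_cohort(cohort_spec("a", 3000, 0.15, missing_rate = 0,
                                        seed = 41),
                            list(planted_signal(desc, 5)), mode = "outcome")
  target <- generate_cohort(cohort_spec("b", 3000, 0.10, missing_rate = 0,
                                        seed = 42),
                            list(planted_signal(desc, 5)), mode = "outcome")
  fit <- mdscan(mm ~ age + sex + bmi, source, rho = 1, restarts = 3, seed = 4)
  tr <- mdscan_transfer(fit, target, source_site = "a", target_site = "b")
  expect_true(tr$robust)
  expect_gt(tr$or, 1)
  # permuted-outcome target: no association left to transfer
  null_target <- target
  set.seed(99); null_target$mm <- sample(null_target$mm)
  tr0 <- mdscan_transfer(fit, null_target)
  expect_false(tr0$robust)
})

test_that("coverage of the Woolf interval is near nominal", {
  set.seed(17)
  n1 <- 400; n2 <- 1600; p1 <- 0.35; p2 <- 0.12
  true_or <- (p1 / (1 - p1)) / (p2 / (1 - p2))
  hits <- 0; reps <- 300
  for (i in seq_len(reps)) {
    a <- rbinom(1, n1, p1); c_ <- rbinom(1, n2, p2)
    ci <- or_ci(c(a, n1 - a, c_, n2 - c_))
    if (!is.na(ci$ci_low) && ci$ci_low <= true_or && true_or <= ci$ci_high)
      hits <- hits + 1
  }
  expect_gt(hits / reps, 0.92)
  expect_lt(hits / reps, 0.985)
})
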