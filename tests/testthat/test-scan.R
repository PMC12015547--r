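test_that("the binomial LR score matches hand-evaluated cases", {
  expect_equal(score_binomial_lr(50, 50, 500), 0)
  expect_equal(score_binomial_lr(78, 37.06, 226), 21.90116, tolerance = 1e-6)
  # C = 0 exercises the 0*log(0) convention
  expect_equal(score_binomial_lr(0, 5, 100), 100 * log(100 / 95))
  expect_error(score_binomial_lr(10, 0, 100), class = "mds_validation_error")
  expect_error(score_binomial_lr(10, 100, 100), class = "mds_validation_error")
})

test_that("the score is non-negative, zero iff C = B, and monotone in C", {
  set.seed(4)
  for (i in 1:50) {
    N <- sample(10:500, 1)
    mu <- runif(1, 0.05, 0.95)
    C <- sample(0:N, 1)
    F <- score_binomial_lr(C, mu * N, N)
    expect_gte(F, 0)
    if (abs(C - mu * N) > 1e-9) expect_gt(F, 0)
  }
  expect_equal(score_binomial_lr(30, 30, 100), 0)
  # moving C away from B in either direction strictly increases F
  Fs <- score_binomial_lr(0:100, rep(40, 101), rep(100, 101))
  expect_true(all(diff(Fs[41:101]) > 0))
  expect_true(all(diff(Fs[1:41]) < 0))
})

test_that("penalized score and literal counting follow the linear penalty", {
  expect_equal(penalized_score(21.90, 2, 0), 21.90)
  expect_equal(penalized_score(21.90, 2, 1.5), 18.90)
  expect_equal(penalized_score(0, 0, 3), 0)
  expect_equal(count_literals(mds_description(mds_literal("sex", "in", "Female"))), 1)
  five <- mds_description(mds_literal("sex", "in", "Female"),
                          mds_literal("age", ">=", 54),
                          mds_literal("bmi", ">=", 23),
                          mds_literal("waist_circumference", ">=", 830),
                          mds_literal("employment", "in", "unemployed"))
  expect_equal(count_literals(five), 5)
  expect_equal(count_literals(mds_description()), 0)
  # a two-sided interval on one feature is two literals
  expect_equal(count_literals(mds_description(mds_literal("age", ">=", 45),
                                              mds_literal("age", "<=", 55))), 2)
  expect_error(mds_description(mds_literal("age", ">=", 45),
                               mds_literal("age", ">=", 50)),
               class = "mds_validation_error")
})

test_that("subset masks are conjunctions and treat missing as exclusion", {
  d <- data.frame(sex = c("F", "F", "F", "M", "M"),
                  age = c(55, 45, NA, 58, 41))
  expect_identical(subset_mask(d, mds_description()), rep(TRUE, 5))
  mf <- subset_mask(d, mds_description(mds_literal("sex", "in", "F")))
  expect_identical(mf, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  ma <- subset_mask(d, mds_description(mds_literal("age", ">=", 50)))
  expect_identical(ma, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  both <- subset_mask(d, mds_description(mds_literal("sex", "in", "F"),
                                         mds_literal("age", ">=", 50)))
  expect_identical(both, mf & ma)
  expect_error(subset_mask(d, mds_description(mds_literal("bmi", ">=", 1))),
               "not present")
})

test_that("per-feature optimization restricts a predictive binary feature", {
  set.seed(9)
  n <- 2000
  g <- sample(c("A", "B"), n, TRUE)
  mm <- rbinom(n, 1, ifelse(g == "A", 0.45, 0.05)) == 1
  d <- data.frame(g = g, mm = mm)
  fit <- mdscan(mm ~ g, d, rho = 0.5, restarts = 1, seed = 1)
  expect_equal(format(fit$description), "g is A")
  low <- mdscan(mm ~ g, d, rho = 0.5, direction = "low", restarts = 1, seed = 1)
  expect_equal(format(low$description), "g is B")
  # a feature independent of the outcome stays unrestricted under penalty
  d$noise <- runif(n)
  fit2 <- mdscan(mm ~ g + noise, d, rho = 3, restarts = 3, seed = 1)
  expect_equal(format(fit2$description), "g is A")
})

test_that("a null cohort under a large penalty returns the whole population", {
  set.seed(5)
  d <- data.frame(x = runif(300), g = sample(LETTERS[1:3], 300, TRUE))
  d$mm <- rbinom(300, 1, 0.2) == 1
  fit <- mdscan(mm ~ x + g, d, rho = 50, restarts = 3, seed = 2)
  expect_equal(count_literals(fit$description), 0)
  expect_equal(fit$F_pen, 0)
  expect_equal(fit$C, fit$B)
})

test_that("scan results satisfy their own invariants", {
  for (seed in 1:5) {
    d <- random_instance(seed)
    for (dir in c("high", "low")) {
      fit <- mdscan(scan_formula(d), d, rho = 0.5, direction = dir,
                    n_bins = 4, restarts = 5, seed = seed)
      expect_gte(fit$F, 0)
      expect_equal(fit$F_pen, fit$F - 0.5 * fit$NL)
      expect_equal(fit$NL, count_literals(fit$description))
      expect_gte(fit$F_pen, 0)   # ascent starts at the whole population
      if (dir == "high") expect_gte(fit$C, fit$B) else expect_lte(fit$C, fit$B)
      # reported counts agree with re-applying the description raw-scale
      m <- predict(fit)
      expect_equal(sum(m), fit$N)
      expect_equal(sum(d$mm[m]), fit$C)
    }
  }
})

test_that("the iterative scan matches the exhaustive oracle on small instances", {
  agree <- 0
  for (seed in 1:20) {
    d <- random_instance(seed, n = 100)
    ex <- exhaustive_mdscan(scan_formula(d), d, rho = 0.3, n_bins = 3)
    it <- mdscan(scan_formula(d), d, rho = 0.3, n_bins = 3,
                 restarts = 20, seed = seed)
    expect_lte(it$F_pen, ex$F_pen + 1e-9)
    if (abs(it$F_pen - ex$F_pen) < 1e-9) agree <- agree + 1
  }
  expect_gte(agree, 19)
})

test_that("the exhaustive oracle respects the direction gate and refuses huge spaces", {
  for (seed in 1:10) {
    d <- random_instance(seed, n = 80)
    ex <- exhaustive_mdscan(scan_formula(d), d, rho = 0.2, n_bins = 3)
    expect_gte(ex$C, ex$B)
    lo <- exhaustive_mdscan(scan_formula(d), d, rho = 0.2, n_bins = 3,
                            direction = "low")
    expect_lte(lo$C, lo$B)
  }
  set.seed(1)
  big <- data.frame(matrix(runif(200 * 8), 200))
  big$mm <- rbinom(200, 1, 0.3) == 1
  expect_error(exhaustive_mdscan(scan_formula(big), big, n_bins = 10,
                                 max_space = 1e4), "too large")
})

test_that("forced literals are kept, excluded from optimization, and counted", {
  set.seed(12)
  n <- 1500
  d <- data.frame(sex = sample(c("Female", "Male"), n, TRUE),
                  age = round(runif(n, 40, 60), 1))
  d$mm <- rbinom(n, 1, ifelse(d$age >= 55, 0.5, 0.1)) == 1
  forced <- mds_description(mds_literal("sex", "in", "Male"))
  fit <- mdscan(mm ~ sex + age, d, rho = 1, restarts = 3, seed = 1,
                forced = forced)
  cf <- coef(fit)
  expect_true(any(cf$feature == "sex" & cf$value == "Male"))
  expect_gte(fit$NL, 1)
  expect_true(all(d$sex[predict(fit)] == "Male"))
})

test_that("degenerate outcomes are rejected with a message", {
  d <- data.frame(x = runif(50), mm = TRUE)
  expect_error(mdscan(mm ~ x, d), "degenerate")
})
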