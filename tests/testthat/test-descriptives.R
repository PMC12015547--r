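test_that("subset statistics match a brute-force tally", {
  d <- data.frame(g = rep(c("A", "B"), each = 20),
                  mm = rep(c(TRUE, FALSE), 20))
  st <- subset_stats(d, mds_description(mds_literal("g", "in", "A")))
  expect_equal(st$a, 10); expect_equal(st$b, 10)
  expect_equal(st$c, 10); expect_equal(st$d, 10)
  expect_equal(st$or, 1); expect_equal(st$p_s, 0.5)

  set.seed(8)
  co <- generate_cohort(cohort_spec("a", 1200, 0.2, missing_rate = 0, seed = 8))
  desc <- mds_description(mds_literal("age", ">=", 50),
                          mds_literal("sex", "in", "Female"))
  st2 <- subset_stats(co, desc)
  s <- co$age >= 50 & !is.na(co$age) & co$sex == "Female" & !is.na(co$sex)
  a <- sum(s & co$mm); b <- sum(s & !co$mm)
  c_ <- sum(!s & co$mm); d_ <- sum(!s & !co$mm)
  expect_equal(c(st2$a, st2$b, st2$c, st2$d), c(a, b, c_, d_))
  expect_equal(st2$or, (a * d_) / (b * c_))
  expect_equal(st2$p_s, (a + b) / 1200)
  expect_equal(st2$p_mm_given_s, a / (a + b))
  expect_equal(st2$p_s_given_mm, a / (a + c_))
})

test_that("identities hold and fraction reconstruction inverts the tally", {
  set.seed(11)
  for (i in 1:20) {
    cells <- rmultinom(1, 400, runif(4, 0.05, 1))[, 1]
    st <- mdscan:::cells_to_stats(cells[1], cells[2], cells[3], cells[4])
    expect_equal(st$a + st$b + st$c + st$d, st$n)
    expect_equal(st$p_s, (st$a + st$b) / st$n, tolerance = 1e-12)
    if (min(cells) > 0) {
      rec <- stats_from_fractions(st$n, (st$a + st$c) / st$n, st$p_s,
                                  st$p_mm_given_s)
      expect_equal(c(rec$a, rec$b, rec$c, rec$d),
                   c(st$a, st$b, st$c, st$d))
    }
  }
  # subset rate equal to the population rate gives OR = 1
  st <- stats_from_fractions(1000, 0.2, 0.3, 0.2)
  expect_equal(st$or, 1, tolerance = 1e-12)
  expect_error(stats_from_fractions(100, 0.5, 0.9, 0.9),
               class = "mds_validation_error")
})

test_that("published worked examples reconstruct from printed fractions", {
  expect_equal(stats_from_fractions(1377, 0.164, 0.164, 0.345)$or,
               3.57, tolerance = 0.002)
  expect_equal(stats_from_fractions(1777, 0.097, 0.084, 0.295)$or,
               4.91, tolerance = 0.002)
})

test_that("a zero cell triggers the flagged Haldane correction", {
  d <- data.frame(g = rep(c("A", "B"), each = 10),
                  mm = rep(c(TRUE, FALSE), each = 10))
  st <- subset_stats(d, mds_description(mds_literal("g", "in", "A")))
  expect_true(st$haldane)
  expect_equal(st$or, (10.5 * 10.5) / (0.5 * 0.5))
  # empty subset: OR undefined, cells still reported
  st0 <- subset_stats(d, mds_description(mds_literal("g", "in", "Z")))
  expect_true(is.na(st0$p_mm_given_s))
  expect_equal(st0$a + st0$b, 0)
})

test_that("venn regions partition the cohort", {
  d <- data.frame(x = c(1, 2, 3, 4, 5, 6), g = c("A", "A", "B", "B", "A", "B"),
                  mm = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  d1 <- mds_description(mds_literal("x", ">=", 4))
  d2 <- mds_description(mds_literal("g", "in", "A"))
  vr <- venn_regions(d, list(d1, d2), female_feature = NULL)
  expect_equal(sum(vr$count), 6)
  # identical descriptions populate only intersection and outside
  vr2 <- venn_regions(d, list(d1, d1), female_feature = NULL)
  expect_equal(nrow(vr2), 2)
  expect_true(all(vr2$S1 == vr2$S2))
  # disjoint descriptions have an empty intersection (region absent)
  d3 <- mds_description(mds_literal("x", "<=", 3))
  vr3 <- venn_regions(d, list(d1, d3), female_feature = NULL)
  expect_false(any(vr3$S1 & vr3$S2))
  # random descriptions against a brute-force tally
  set.seed(14)
  co <- generate_cohort(cohort_spec("a", 600, 0.2, missing_rate = 0, seed = 14))
  ds <- list(mds_description(mds_literal("age", ">=", 52)),
             mds_description(mds_literal("sex", "in", "Female")),
             mds_description(mds_literal("bmi", "<=", 27)))
  vr4 <- venn_regions(co, ds, female_feature = NULL)
  expect_equal(sum(vr4$count), 600)
  m <- sapply(ds, function(x) subset_mask(co, x))
  key <- apply(m, 1, paste, collapse = "")
  expect_setequal(vr4$count, as.integer(table(key)))
})
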