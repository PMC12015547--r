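# Fixtures built in code: no stored data files.

# A raw phenotyping row with healthy defaults; override any field.
raw_row <- function(...) {
  row <- list(age = 50, sex = "Female", sbp = 120, dbp = 75, on_ht_meds = FALSE,
              fasting_glucose = 5, random_glucose = 6, dm_prior_dx = FALSE,
              on_dm_meds = FALSE, creatinine = 0.8, uacr = 1,
              heart_attack = FALSE, stroke_or_tia = FALSE, chf = FALSE,
              angina = FALSE)
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, stringsAsFactors = FALSE)
}

raw_cohort <- function(...) do.call(rbind, list(...))

# Small random scan instance: numeric + categorical features, Bernoulli outcome.
random_instance <- function(seed, n = 120, p_num = 2, p_cat = 1,
                            cat_levels = 3, rate = 0.3) {
  set.seed(seed)
  d <- data.frame(row.names = seq_len(n))
  for (j in seq_len(p_num)) d[[paste0("x", j)]] <- round(stats::runif(n), 2)
  for (j in seq_len(p_cat))
    d[[paste0("g", j)]] <- sample(LETTERS[seq_len(cat_levels)], n, TRUE)
  d$mm <- stats::rbinom(n, 1, rate) == 1
  if (sum(d$mm) == 0) d$mm[1] <- TRUE
  if (sum(!d$mm) == 0) d$mm[1] <- FALSE
  d
}

scan_formula <- function(d) stats::reformulate(setdiff(names(d), "mm"), "mm")

# central 99% probability interval for an empirical proportion at true p
binom99 <- function(n, p) {
  c(stats::qbinom(0.005, n, p), stats::qbinom(0.995, n, p)) / n
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
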