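# Two-site synthetic cohort generator with planted high-/low-risk subsets.
#
# The generator emulates the statistical structure the scan assumes: realistic
# feature marginals, a baseline Bernoulli multimorbidity outcome, and ground
# truth in the form of conjunctive subsets whose outcome odds are multiplied
# by a known factor.  Every random draw comes from a named sub-stream of the
# master seed, so adding a feature never perturbs the outcome draw.

#' Default feature marginals for the synthetic cohort
#'
#' Age is uniform on the inclusion window; BMI, waist circumference and
#' triglycerides (and the other lipids and fat depots) are log-normal; CIMT
#' is normal truncated at zero; categorical features are multinomial.  Only
#' ranges and units matter downstream (thresholds are rendered on the raw
#' scale); the marginals are chosen to be plausible for a middle-aged
#' sub-Saharan survey cohort, not to match any real covariance structure.
#'
#' @return a named list of feature specifications, each a list with `kind`
#'   (`"continuous"`, `"categorical"`, `"ordinal"`) and distribution
#'   parameters.
#' @export
default_feature_specs <- function() {
  list(
    age = list(kind = "continuous", dist = "uniform", min = 40, max = 60),
    sex = list(kind = "categorical", levels = c("Female", "Male"),
               prob = c(0.55, 0.45)),
    bmi = list(kind = "continuous", dist = "lognormal",
               meanlog = log(26), sdlog = 0.25),
    waist_circumference = list(kind = "continuous", dist = "lognormal",
                               meanlog = log(870), sdlog = 0.15),
    waist_hip_ratio = list(kind = "continuous", dist = "normal",
                           mean = 0.91, sd = 0.07, min = 0),
    cimt_mean_max = list(kind = "continuous", dist = "normal",
                         mean = 0.64, sd = 0.12, min = 0),
    tc = list(kind = "continuous", dist = "lognormal",
              meanlog = log(4.6), sdlog = 0.22),
    ldl = list(kind = "continuous", dist = "lognormal",
               meanlog = log(2.8), sdlog = 0.30),
    hdl = list(kind = "continuous", dist = "lognormal",
               meanlog = log(1.3), sdlog = 0.28),
    triglycerides = list(kind = "continuous", dist = "lognormal",
                         meanlog = log(1.1), sdlog = 0.45),
    vat = list(kind = "continuous", dist = "lognormal",
               meanlog = log(4.3), sdlog = 0.40),
    scat = list(kind = "continuous", dist = "lognormal",
                meanlog = log(19), sdlog = 0.40),
    hiv_status = list(kind = "categorical", levels = c("Negative", "Positive"),
                      prob = c(0.80, 0.20)),
    education = list(kind = "categorical",
                     levels = c("none", "primary", "secondary", "tertiary"),
                     prob = c(0.25, 0.40, 0.30, 0.05)),
    partnership = list(kind = "categorical",
                       levels = c("married", "single", "widowed_divorced"),
                       prob = c(0.55, 0.20, 0.25)),
    ses_quintile = list(kind = "ordinal", levels = 1:5, prob = rep(0.2, 5)),
    employment = list(kind = "categorical",
                      levels = c("employed", "informal", "unemployed"),
                      prob = c(0.35, 0.25, 0.40)),
    mvpa = list(kind = "categorical", levels = c("low", "moderate", "high"),
                prob = c(0.40, 0.35, 0.25)),
    alcohol = list(kind = "categorical", levels = c("never", "former", "current"),
                   prob = c(0.50, 0.15, 0.35)),
    smoking = list(kind = "categorical", levels = c("never", "former", "current"),
                   prob = c(0.70, 0.12, 0.18))
  )
}

#' Specify a synthetic cohort
#'
#' @param site_label site name recorded in the `site` column.
#' @param n number of participants (>= 10).
#' @param baseline_rate population multimorbidity rate `mu`, strictly in (0, 1).
#' @param feature_specs named list of feature marginals
#'   (see [default_feature_specs()]); names must be unique.
#' @param missing_rate per-cell missingness probability in [0, 0.05].
#' @param seed non-negative master seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(site_label, n, baseline_rate,
                        feature_specs = default_feature_specs(),
                        missing_rate = 0.01, seed = 1) {
  stopifnot(is.character(site_label), length(site_label) == 1L)
  if (!is.numeric(n) || n < 10) stop_validation("n must be >= 10")
  check_prob(baseline_rate, "baseline_rate")
  if (missing_rate < 0 || missing_rate > 0.05)
    stop_validation("missing_rate must lie in [0, 0.05]")
  if (anyDuplicated(names(feature_specs)))
    stop_validation("feature names must be unique")
  structure(list(site_label = site_label, n = as.integer(n),
                 baseline_rate = baseline_rate, feature_specs = feature_specs,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Plant a known high- or low-risk subset
#'
#' @param description an [mds_description()]; rows satisfying it have their
#'   outcome odds multiplied by `odds_multiplier` (> 1 plants high risk,
#'   < 1 low risk).
#' @param odds_multiplier positive real.
#' @return an object of class `planted_signal`.
#' @export
planted_signal <- function(description, odds_multiplier) {
  stopifnot(inherits(description, "mds_description"))
  if (!is.numeric(odds_multiplier) || odds_multiplier <= 0)
    stop_validation("odds_multiplier must be positive")
  structure(list(description = description, odds_multiplier = odds_multiplier),
            class = "planted_signal")
}

draw_feature <- function(fs, n) {
  switch(fs$kind,
    continuous = switch(fs$dist,
      uniform = stats::runif(n, fs$min, fs$max),
      lognormal = stats::rlnorm(n, fs$meanlog, fs$sdlog),
      normal = rtnorm(n, fs$mean, fs$sd, lower = fs$min %||% -Inf),
      stop("unknown distribution: ", fs$dist)),
    categorical = sample(fs$levels, n, replace = TRUE, prob = fs$prob),
    ordinal = sample(fs$levels, n, replace = TRUE, prob = fs$prob),
    stop("unknown feature kind: ", fs$kind))
}

#' Generate a synthetic raw cohort with planted signals
#'
#' Draws the feature table from the spec's marginals, then plants the signals:
#' each row's outcome odds are the baseline odds times the product of the
#' odds multipliers of every signal whose description the row satisfies.
#'
#' In `"outcome"` mode the multimorbidity column `mm` is drawn directly from
#' those odds (the raw biomarker columns are generated at the baseline
#' condition rates and are not linked to `mm`) — this is the mode for testing
#' the scan itself.  In `"biomarker"` mode the planted odds act on each of
#' the four conditions; condition statuses are drawn, the raw biomarkers
#' (blood pressures, glucose, creatinine, albuminuria, self-report flags)
#' are rendered consistently with them, and `mm` follows from phenotyping —
#' this is the mode for end-to-end tests.  A common logit shift on the four
#' condition prevalences is calibrated by root finding so the expected
#' multimorbidity rate matches `baseline_rate`.
#'
#' @param spec a [cohort_spec()].
#' @param signals list of [planted_signal()]s; descriptions may only
#'   reference features of the spec.
#' @param mode `"outcome"` or `"biomarker"` (see Details).
#' @return a data frame (`id`, `site`, features, raw phenotyping inputs,
#'   `mm`) with attribute `truth` holding the per-row planted odds multiplier.
#'   Identical `(spec, signals)` give identical output.
#' @export
generate_cohort <- function(spec, signals = list(),
                            mode = c("outcome", "biomarker")) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  if (inherits(signals, "planted_signal")) signals <- list(signals)
  n <- spec$n
  df <- data.frame(id = paste0(spec$site_label, "_", seq_len(n)),
                   site = spec$site_label, stringsAsFactors = FALSE)
  for (f in names(spec$feature_specs)) {
    set.seed(substream_seed(spec$seed, paste0("feature:", f)))
    df[[f]] <- draw_feature(spec$feature_specs[[f]], n)
  }
  for (sg in signals) {
    stopifnot(inherits(sg, "planted_signal"))
    bad <- setdiff(vapply(sg$description$literals, `[[`, "", "feature"),
                   names(spec$feature_specs))
    if (length(bad))
      stop("planted signal references unknown feature(s): ",
           paste(bad, collapse = ", "))
  }
  mult <- rep(1, n)
  for (sg in signals)
    mult <- mult * ifelse(subset_mask(df, sg$description), sg$odds_multiplier, 1)

  if (mode == "outcome") {
    p <- stats::plogis(stats::qlogis(spec$baseline_rate) + log(mult))
    set.seed(substream_seed(spec$seed, "outcome"))
    df$mm <- stats::rbinom(n, 1, p) == 1
    df <- render_biomarkers(df, cond_probs(spec, rep(1, n)), spec$seed)
  } else {
    probs <- cond_probs(spec, mult)
    df <- render_biomarkers(df, probs, spec$seed)
    df$mm <- with(df, derive_multimorbidity(
      classify_hypertension(sbp, dbp, on_ht_meds),
      classify_diabetes(fasting_glucose, random_glucose, dm_prior_dx, on_dm_meds),
      classify_ckd(egfr_ckd_epi(creatinine, age, sex), uacr),
      classify_cvd(heart_attack, stroke_or_tia, chf, angina)))
  }
  if (spec$missing_rate > 0)
    df <- inject_missingness(df, spec$missing_rate,
                             seed = substream_seed(spec$seed, "missingness"))
  attr(df, "truth") <- mult
  df
}

# Per-row condition probabilities: site-specific base rates (hypertension
# dominant), a planted per-row odds multiplier on every condition, and a
# common logit shift t calibrated so that mean P(>= 2 conditions) under
# conditional independence equals the target multimorbidity rate.
cond_probs <- function(spec, mult) {
  base <- c(ht = 0.40, dm = 0.07, ckd = 0.12, cvd = 0.035)
  lmult <- log(mult)
  p_mm <- function(t) {
    P <- vapply(base, function(b) stats::plogis(stats::qlogis(b) + t + lmult),
                numeric(length(mult)))
    q <- 1 - P
    p0 <- q[, 1] * q[, 2] * q[, 3] * q[, 4]
    p1 <- rowSums(vapply(1:4, function(j) {
      pj <- P[, j] / q[, j] * p0
      pj
    }, numeric(length(mult))))
    mean(1 - p0 - p1)
  }
  t <- stats::uniroot(function(t) p_mm(t) - spec$baseline_rate,
                      lower = -8, upper = 8, tol = 1e-10)$root
  vapply(base, function(b) stats::plogis(stats::qlogis(b) + t + lmult),
         numeric(length(mult)))
}

# Draw condition statuses and render raw biomarkers consistent with them.
# Values are drawn strictly on the correct side of each diagnostic threshold,
# so phenotyping reproduces the planted statuses exactly.
render_biomarkers <- function(df, probs, seed) {
  n <- nrow(df)
  status <- matrix(FALSE, n, 4, dimnames = list(NULL, colnames(probs)))
  for (j in colnames(probs)) {
    set.seed(substream_seed(seed, paste0("condition:", j)))
    status[, j] <- stats::runif(n) < probs[, j]
  }
  set.seed(substream_seed(seed, "biomarkers"))
  ht <- status[, "ht"]
  df$sbp <- ifelse(ht, rtnorm(n, 155, 12, lower = 141),
                   rtnorm(n, 119, 9, upper = 139.4))
  df$dbp <- ifelse(ht, rtnorm(n, 92, 8), rtnorm(n, 76, 7, upper = 89.4))
  df$on_ht_meds <- ht & stats::runif(n) < 0.30

  dm <- status[, "dm"]
  df$fasting_glucose <- ifelse(dm, rtnorm(n, 9.5, 2, lower = 7.05),
                               rtnorm(n, 5.2, 0.6, upper = 6.9))
  df$random_glucose <- ifelse(dm, rtnorm(n, 12, 3, lower = 4),
                              rtnorm(n, 6.5, 1.5, lower = 2, upper = 11))
  df$dm_prior_dx <- dm & stats::runif(n) < 0.40
  df$on_dm_meds <- dm & stats::runif(n) < 0.30

  ckd <- status[, "ckd"]
  egfr_path <- ckd & stats::runif(n) < 0.60
  egfr_target <- ifelse(ckd,
                        ifelse(egfr_path, stats::runif(n, 25, 60),
                               stats::runif(n, 70, 110)),
                        stats::runif(n, 75, 120))
  df$creatinine <- creatinine_from_egfr(egfr_target, df$age, df$sex)
  df$uacr <- ifelse(ckd & !egfr_path, stats::runif(n, 3.2, 30),
                    stats::runif(n, 0.1, 2.8))

  cvd <- status[, "cvd"]
  which_flag <- sample.int(4L, n, replace = TRUE)
  df$heart_attack <- cvd & which_flag == 1L
  df$stroke_or_tia <- cvd & which_flag == 2L
  df$chf <- cvd & which_flag == 3L
  df$angina <- cvd & which_flag == 4L
  df
}

# invert the CKD-EPI 2009 equation: creatinine (mg/dL) giving a target eGFR
creatinine_from_egfr <- function(egfr, age, sex) {
  female <- substr(tolower(as.character(sex)), 1L, 1L) == "f"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  base <- 141 * 0.993^age * ifelse(female, 1.018, 1)
  ratio <- egfr / base
  # ratio >= 1 needs Scr < kappa (exponent alpha); else Scr > kappa (-1.209)
  ifelse(ratio >= 1, kappa * ratio^(1 / alpha), kappa * ratio^(-1 / 1.209))
}

#' Mask feature cells at random (missing-data emulation)
#'
#' Each cell of the feature and raw-input columns is masked independently
#' with probability `rate`, except that a row is never left with all four
#' conditions' inputs missing at once (if masking would do so, that row's
#' self-report flags are restored).  Identifier, site and outcome columns are
#' never masked.
#'
#' @param cohort a data frame from [generate_cohort()].
#' @param rate masking probability in [0, 0.05].
#' @param seed integer seed.
#' @return the cohort with `NA`s injected; row count unchanged.
#' @export
inject_missingness <- function(cohort, rate, seed = 1) {
  if (!is.numeric(rate) || rate < 0 || rate > 0.05)
    stop_validation("rate must lie in [0, 0.05]")
  if (rate == 0) return(cohort)
  protect <- c("id", "site", "mm")
  cols <- setdiff(names(cohort), protect)
  set.seed(seed)
  out <- cohort
  for (cl in cols) {
    hit <- stats::runif(nrow(out)) < rate
    out[[cl]][hit] <- NA
  }
  groups <- list(ht = c("sbp", "dbp", "on_ht_meds"),
                 dm = c("fasting_glucose", "random_glucose", "dm_prior_dx",
                        "on_dm_meds"),
                 ckd = c("creatinine", "uacr"),
                 cvd = c("heart_attack", "stroke_or_tia", "chf", "angina"))
  groups <- lapply(groups, intersect, names(out))
  if (all(lengths(groups) > 0)) {
    all_missing <- Reduce(`&`, lapply(groups, function(g)
      apply(is.na(out[, g, drop = FALSE]), 1L, all)))
    if (any(all_missing))
      out[all_missing, groups$cvd] <- cohort[all_missing, groups$cvd]
  }
  out
}

#' Simulate the two-site study
#'
#' Convenience wrapper producing the two cohorts the analysis is designed
#' around: a higher-prevalence site (baseline multimorbidity 16.4%, n = 1465
#' before inclusion) and a lower-prevalence site (9.7%, n = 1942), with <= 1%
#' per-cell missingness.
#'
#' @param seed master seed; each site uses a named sub-stream.
#' @param n per-site sizes (length 2).
#' @param baseline per-site multimorbidity rates (length 2).
#' @param site_labels site names.
#' @param mode passed to [generate_cohort()].
#' @param missing_rate per-cell missingness.
#' @param signals named list (by site label) of lists of [planted_signal()]s.
#' @return a named list of two raw cohorts.
#' @export
simulate_two_site_study <- function(seed = 1, n = c(1465, 1942),
                                    baseline = c(0.164, 0.097),
                                    site_labels = c("site_a", "site_b"),
                                    mode = "biomarker", missing_rate = 0.01,
                                    signals = list()) {
  out <- lapply(1:2, function(i) {
    sp <- cohort_spec(site_labels[i], n[i], baseline[i],
                      missing_rate = missing_rate,
                      seed = substream_seed(seed, paste0("site:", site_labels[i])))
    generate_cohort(sp, signals[[site_labels[i]]] %||% list(), mode = mode)
  })
  names(out) <- site_labels
  out
}
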