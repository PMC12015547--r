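# Condition phenotyping from raw survey and biomarker inputs.
#
# All classifiers are "or"-compositions of criteria and share one missing-data
# semantics (Kleene OR): a condition is present if any criterion is met,
# absent only when every criterion is observed and unmet, and NA otherwise.
# Complete-case filtering happens once, on the four condition flags, in
# apply_inclusion()/phenotype_cohort().

#' Classify hypertension (JNC-7 thresholds)
#'
#' Present iff systolic blood pressure >= 140 mmHg, or diastolic >= 90 mmHg,
#' or the participant is on hypertension medication.
#'
#' @param sbp,dbp systolic/diastolic blood pressure in mmHg (positive or `NA`).
#' @param on_ht_meds logical medication flag.
#' @return logical vector (with `NA` where the flag is undecidable).
#' @export
classify_hypertension <- function(sbp, dbp, on_ht_meds) {
  if (any(sbp <= 0 | dbp <= 0, na.rm = TRUE))
    stop_validation("blood pressures must be positive")
  or3(sbp >= 140, dbp >= 90, as.logical(on_ht_meds))
}

#' Classify diabetes mellitus (WHO criteria)
#'
#' Present iff a prior diagnosis, fasting glucose >= 7 mmol/L, random glucose
#' >= 11.1 mmol/L, or on diabetes medication.
#'
#' @param fasting_glucose,random_glucose plasma glucose in mmol/L.
#' @param prior_dx,on_dm_meds logical flags.
#' @export
classify_diabetes <- function(fasting_glucose, random_glucose, prior_dx,
                              on_dm_meds) {
  if (any(fasting_glucose < 0 | random_glucose < 0, na.rm = TRUE))
    stop_validation("glucose values must be non-negative")
  or3(as.logical(prior_dx), fasting_glucose >= 7,
      random_glucose >= 11.1, as.logical(on_dm_meds))
}

#' Estimated GFR, CKD-EPI creatinine equation (2009), no race coefficient
#'
#' \deqn{eGFR = 141 \cdot \min(Scr/\kappa, 1)^{\alpha} \cdot
#'   \max(Scr/\kappa, 1)^{-1.209} \cdot 0.993^{age} \cdot 1.018[female]}
#' with \eqn{(\kappa, \alpha)} = (0.7, -0.329) for women and (0.9, -0.411)
#' for men.  Creatinine may be supplied in mg/dL or in umol/L (divided by
#' 88.4).
#'
#' @param creatinine serum creatinine (> 0).
#' @param age age in years (> 0).
#' @param sex `"Female"`/`"Male"` (case-insensitive, `"F"`/`"M"` accepted).
#' @param unit `"mg/dL"` (default) or `"umol/L"`.
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' egfr_ckd_epi(0.8, 50, "Female")   # ~ 86.0
#' @export
egfr_ckd_epi <- function(creatinine, age, sex, unit = c("mg/dL", "umol/L")) {
  unit <- match.arg(unit)
  if (any(creatinine <= 0 | age <= 0, na.rm = TRUE))
    stop_validation("creatinine and age must be positive")
  if (unit == "umol/L") creatinine <- creatinine / 88.4
  female <- substr(tolower(as.character(sex)), 1L, 1L) == "f"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  r <- creatinine / kappa
  141 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.209) * 0.993^age *
    ifelse(female, 1.018, 1)
}

#' Classify chronic kidney disease
#'
#' Present iff eGFR <= 60 mL/min/1.73 m^2 (inclusive, as applied here) or
#' albuminuria (urine albumin-creatinine ratio > 3 mg/mmol), either alone
#' sufficing.
#'
#' @param egfr estimated GFR (see [egfr_ckd_epi()]).
#' @param uacr urine albumin-creatinine ratio in mg/mmol.
#' @export
classify_ckd <- function(egfr, uacr) {
  if (any(egfr < 0 | uacr < 0, na.rm = TRUE))
    stop_validation("egfr and uacr must be non-negative")
  or3(egfr <= 60, uacr > 3)
}

#' Classify cardiovascular disease from self-reported history
#'
#' Present iff the participant reports a heart attack, stroke or transient
#' ischaemic attack, congestive heart failure, or angina.
#'
#' @param heart_attack,stroke_or_tia,chf,angina logical flags.
#' @export
classify_cvd <- function(heart_attack, stroke_or_tia, chf, angina) {
  or3(as.logical(heart_attack), as.logical(stroke_or_tia),
      as.logical(chf), as.logical(angina))
}

#' Derive the multimorbidity outcome from the four condition flags
#'
#' Multimorbidity is the presence of at least two of hypertension, diabetes,
#' chronic kidney disease and cardiovascular disease.  Rows with a missing
#' flag get `NA` (they are excluded by the inclusion filter, never imputed).
#'
#' @param ht,dm,ckd,cvd logical condition flags.
#' @export
derive_multimorbidity <- function(ht, dm, ckd, cvd) {
  m <- cbind(ht, dm, ckd, cvd)
  out <- rowSums(m) >= 2
  out[apply(is.na(m), 1L, any)] <- NA
  out
}

#' Phenotype a raw cohort and apply the inclusion filters
#'
#' Derives the four condition flags and the multimorbidity outcome from the
#' raw columns (`sbp`, `dbp`, `on_ht_meds`, `fasting_glucose`,
#' `random_glucose`, `dm_prior_dx`, `on_dm_meds`, `creatinine`, `uacr`,
#' `heart_attack`, `stroke_or_tia`, `chf`, `angina`, `age`, `sex`), then
#' retains rows within the age range (inclusive on both ends) whose four
#' flags are all derivable.  The observed multimorbidity rate `mu` and the
#' retention fraction are attached as attributes.
#'
#' @param raw a data frame of raw phenotyping inputs plus scan features.
#' @param creatinine_unit `"mg/dL"` or `"umol/L"`.
#' @param age_range inclusive age filter, default `c(40, 60)`.
#' @return the phenotyped cohort: `raw`'s rows (filtered) plus logical
#'   columns `ht`, `dm`, `ckd`, `cvd`, `mm` and numeric `egfr`, with
#'   attributes `mu`, `retention`, `n_raw`.
#' @export
phenotype_cohort <- function(raw, creatinine_unit = c("mg/dL", "umol/L"),
                             age_range = c(40, 60)) {
  creatinine_unit <- match.arg(creatinine_unit)
  need <- c("age", "sex", "sbp", "dbp", "on_ht_meds", "fasting_glucose",
            "random_glucose", "dm_prior_dx", "on_dm_meds", "creatinine",
            "uacr", "heart_attack", "stroke_or_tia", "chf", "angina")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("raw cohort lacks phenotyping columns: ", paste(miss, collapse = ", "))
  out <- raw
  out$ht <- classify_hypertension(raw$sbp, raw$dbp, raw$on_ht_meds)
  out$dm <- classify_diabetes(raw$fasting_glucose, raw$random_glucose,
                              raw$dm_prior_dx, raw$on_dm_meds)
  out$egfr <- egfr_ckd_epi(raw$creatinine, raw$age, raw$sex,
                           unit = creatinine_unit)
  out$ckd <- classify_ckd(out$egfr, raw$uacr)
  out$cvd <- classify_cvd(raw$heart_attack, raw$stroke_or_tia,
                          raw$chf, raw$angina)
  out$mm <- derive_multimorbidity(out$ht, out$dm, out$ckd, out$cvd)
  in_age <- !is.na(raw$age) & raw$age >= age_range[1L] & raw$age <= age_range[2L]
  keep <- in_age & !is.na(out$mm) &
    !is.na(out$ht) & !is.na(out$dm) & !is.na(out$ckd) & !is.na(out$cvd)
  res <- out[keep, , drop = FALSE]
  if (nrow(res) == 0L) stop("no rows satisfy the inclusion criteria")
  rownames(res) <- NULL
  attr(res, "mu") <- mean(res$mm)
  attr(res, "retention") <- sum(keep) / sum(in_age)
  attr(res, "n_raw") <- nrow(raw)
  res
}

#' Exact condition-combination (UpSet) counts
#'
#' Counts participants by their exact combination of the four conditions.
#' The counts over all 15 non-empty combinations partition the set of
#' participants with at least one condition.
#'
#' @param cohort a phenotyped cohort with logical `ht`, `dm`, `ckd`, `cvd`.
#' @return a named integer vector over the 15 combinations
#'   (`"HT"`, `"HT+DM"`, ..., `"HT+DM+CKD+CVD"`), zeros included.
#' @export
cooccurrence_counts <- function(cohort) {
  stopifnot(all(c("ht", "dm", "ckd", "cvd") %in% names(cohort)),
            nrow(cohort) > 0)
  flags <- as.matrix(cohort[, c("ht", "dm", "ckd", "cvd")]) == TRUE
  labels <- c("HT", "DM", "CKD", "CVD")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 4L))[-1L, 4:1]
  nm <- apply(combos, 1L, function(r) paste(labels[unlist(r)], collapse = "+"))
  counts <- vapply(seq_len(nrow(combos)), function(i) {
    want <- unlist(combos[i, ])
    sum(apply(flags, 1L, function(r) all(r == want)))
  }, 0L)
  names(counts) <- nm
  counts
}
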