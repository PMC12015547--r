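Package: mdscan
Title: Automatic Stratification of Multimorbidity Risk by Penalized Subset Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers sub-populations of a survey cohort with anomalously high or
    low rates of multimorbidity by maximizing a penalized binomial likelihood-ratio
    scan statistic over conjunctive subset descriptions (multidimensional subset
    scanning with per-feature linear-time optimization and random restarts).
    Includes phenotyping of hypertension, diabetes, chronic kidney disease and
    cardiovascular disease from raw survey and biomarker inputs (JNC-7, WHO and
    CKD-EPI 2009 criteria), randomization-based significance testing with empirical
    p-values, descriptive statistics for discovered subsets (odds ratios, subset
    coverage, Venn region summaries), cross-cohort transferability checks with
    Woolf confidence intervals, and a two-site synthetic cohort generator with
    planted high- and low-risk subsets for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
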