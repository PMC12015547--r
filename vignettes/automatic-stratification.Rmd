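---
title: "Automatic stratification of multimorbidity risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic stratification of multimorbidity risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdscan)
```

## The problem

Epidemiological cohorts are routinely stratified by hand — outcome rates
compared between "old vs. young" or "male vs. female" — to find
sub-populations at unusually high or low risk. Manual stratification explores
only a handful of pre-conceived strata, one feature at a time, and offers no
principled way to compare candidate subgroups against each other. `mdscan`
automates this: it searches the space of *conjunctive* sub-population
descriptions (e.g. `age >= 53 & waist_circumference >= 950`) for the subset
whose binary outcome rate diverges most from the cohort average, scores every
candidate with a single likelihood-ratio statistic, and controls the
selection effect of searching exponentially many subsets with a
randomization test.

The outcome the package is built around is multimorbidity (MM): the presence
of at least two of hypertension (HT), diabetes mellitus (DM), chronic kidney
disease (CKD) and cardiovascular disease (CVD), phenotyped from raw survey
and biomarker inputs. The machinery is generic for any binary outcome.

## The scan statistic

For a subset $S$ of a cohort with observed outcome count $C(S)$, size
$|S|$, and expected count $B(S) = \mu\,|S|$ under the cohort-wide outcome
rate $\mu$, the score is the binomial likelihood-ratio divergence

$$F(S) = C \log\frac{C}{B} + (|S|-C)\,\log\frac{|S|-C}{|S|-B},$$

with natural logarithms and $0\log 0 := 0$. $F$ is $|S|$ times the
Kullback–Leibler divergence between Bernoulli($C/|S|$) and
Bernoulli($B/|S|$): non-negative, and zero exactly when the subset's rate
equals the population rate. It grows both when $C \gg B$ and when
$C \ll B$, so the high-/low-risk distinction is *not* carried by the score.
High-risk subsets are found by maximizing $F$ over subsets with $C \ge B$
(the direction gate); low-risk subsets by the same maximization with the
gate reversed — never by minimizing $F$, which would simply find the most
average subset. Inside the ascent the gate is applied with a relative
tolerance of $10^{-9}$ on $B$, because $B = \mu |S|$ carries floating-point
error even for the whole population, where $C = B$ holds exactly in exact
arithmetic.

Description complexity is measured by the literal count $NL(S)$ — one per
one-sided threshold, one per categorical level-set, two for a two-sided
interval on one feature — and penalized linearly:

$$F_{pen}(S) = F(S) - \rho\, NL(S), \qquad \rho \ge 0.$$

$\rho$ behaves like a regularization constant: large values force short,
interpretable descriptions; $\rho = 0$ recovers the unpenalized scan.
There is no canonical value — the intended use is a sweep (`rho` in
`run_pipeline()` accepts a vector) reporting how the discovered subsets
change with description length, typically over `NL` 2–4.

## Maximization

The search space is all conjunctions of per-feature restrictions: one-sided
raw-scale thresholds on ordered features (two-sided intervals are supported
via `allow_intervals` but off by default, since one-sided thresholds are the
canonical description language), and level subsets on categorical features.
`mdscan()` maximizes $F_{pen}$ by iterative ascent:

1. Start from the whole population (restart 1) or a seeded random
   single-literal description (later restarts).
2. Sweep the features in seeded random order. For each feature, holding the
   other literals fixed, evaluate all of its candidate restrictions and keep
   the best. For an ordered feature with $k$ bins these are the $2(k-1)$
   one-sided bin runs; for a categorical feature the ALTSS property
   (additive linear-time subset scanning) guarantees the optimal level
   subset is a prefix of the levels sorted by their observed/expected ratio
   $C_v/B_v$, so only $k-1$ prefixes need scoring. "Unrestricted" is always
   a candidate; wrong-side candidates are ineligible.
3. Repeat sweeps until a full pass improves $F_{pen}$ by at most `tol`
   ($10^{-9}$ absolute; equal-score steps that drop literals are taken, which
   cannot cycle because the literal count strictly decreases between score
   jumps).
4. Return the best restart, breaking ties by higher $F_{pen}$, fewer
   literals, smaller subset, then lexicographic description text.

Each accepted step weakly increases $F_{pen}$, which is bounded above, so
the ascent terminates. The procedure is a local optimizer; restarts (default
50) are the defense against local optima. `exhaustive_mdscan()` enumerates
the full description space on small instances and is the ground truth the
ascent is tested against: at the default restarts the two agree on 97 of 100
random 3-feature instances, and the ascent never exceeds the oracle (the
remaining gap is genuine local optima, documented rather than hidden).
Forced literals (e.g. constraining `sex is Female` throughout, for
sex-stratified scans) are held fixed, excluded from optimization, and still
counted in $NL$.

## Discretization and rendering

Continuous features are cut into at most `n_bins` (default 10) left-closed,
right-open quantile bins, with edges at order statistics
$x_{(\lfloor jn/k \rfloor + 1)}$ so bin populations differ by at most one
when values are distinct; duplicate edges from tied data are collapsed. The
default of 10 bins keeps every threshold at a decile of the source cohort —
fine enough to express the reported kinds of subsets, coarse enough that
each candidate retains a meaningful population.

Two choices matter for interpretability and transfer:

* **Raw-scale rendering.** A suffix of bins renders as `feature >= edge`; a
  prefix as `feature <= p` where `p` is the *predecessor* of the edge (the
  largest observed value strictly below it). This makes the rendered
  raw-scale literal select *exactly* the rows of the encoded bin range —
  bit-equal membership masks, ties included — so a description discovered at
  one site can be re-applied verbatim at another with no re-binning, and the
  codebook JSON (17 significant digits, bit-exact round trip) is portable.
* **Missing as exclusion.** A literal is a positive assertion: rows missing
  a restricted feature are excluded from the subset. Missingness is a
  pseudo-level (encoded 0) that no literal can select.

## Significance testing

The scan examines exponentially many subsets, so the best score is inflated
by selection; classical multiplicity corrections over an exponential
hypothesis family are hopelessly conservative. Instead `mdscan_significance()`
uses randomization: each of $K$ (default 100) replica cohorts keeps every
feature and replaces the outcome with i.i.d. Bernoulli($\mu$) coin tosses —
the null that every subset's outcomes are drawn at the population rate. The
*full scan, identical configuration* is re-run on every replica, and

$$p = \frac{r + 1}{K + 1}, \qquad
  r = \#\{k : F(S_k) \ge F(S^*)\}.$$

Because the replica statistic is the same deterministic function of a
dataset as the real statistic, the $K+1$ scores are exchangeable under the
null and $p$ is valid (super-uniform): $P(p \le \alpha) \le \alpha$ on the
support grid. The smallest attainable value is $1/(K+1)$ — at $K = 100$,
$p = 1/101 \approx 0.01$, which is what a strongly planted signal attains.
Each scan (one site, one direction, one $\rho$) is tested against its own
replica distribution. The raw scores $F$, not $F_{pen}$, are compared; with
a common $\rho$ on both sides this choice only relabels the same
exchangeable statistic.

## Descriptive statistics and transfer

For any description, `subset_stats()` reports the 2×2 cells and the derived
quantities used to present discovered subsets: the odds ratio
$OR = ad/bc$, the subset's relative size $P(S)$, its outcome rate
$P(MM\mid S)$, and the share of all cases it contains $P(S\mid MM)$.
`stats_from_fractions()` inverts a published results row — nearest-integer
rounding of the expected cells from $(n, \mu, P(S), P(MM|S))$ — which is how
printed odds ratios are verified from printed three-decimal fractions.
Note the limits of that inversion: at $n \approx 1800$, three-decimal
fractions quantize cells coarsely enough that some printed rows cannot be
reproduced beyond ±2%; the worked examples in the tests use the rows that
are reconstructible at printed precision. `venn_regions()` partitions the
cohort by membership in up to four descriptions, the numeric content of the
overlap diagrams used to compare subsets of different description lengths.

`mdscan_transfer()` re-applies a description verbatim (raw scale, literal by
literal) to a target cohort and judges robustness by whether the Woolf
interval for the target OR,
$\exp(\ln OR \pm z_{0.975}\sqrt{1/a + 1/b + 1/c + 1/d})$, excludes 1.0.
Woolf was chosen because the interval's published reconstruction matches it
to printed precision; a logistic-fit interval differs by less than the
printed rounding on the same cells. Zero cells get the Haldane–Anscombe
correction (0.5 to every cell), always flagged in the result.

## Phenotyping rules

Conditions are "or"-compositions of criteria with three-valued missing-data
logic: present if any criterion is met, absent only when every criterion is
observed and unmet, unknown otherwise.

* **HT**: SBP ≥ 140 mmHg, or DBP ≥ 90 mmHg, or on antihypertensive
  medication (JNC-7). Medication alone suffices, i.e. controlled
  hypertension still counts as hypertensive — implemented as stated, though
  coding practices differ between surveys.
* **DM**: prior diagnosis, fasting glucose ≥ 7 mmol/L, random glucose
  ≥ 11.1 mmol/L, or on diabetes medication (WHO).
* **CKD**: eGFR ≤ 60 mL/min/1.73 m² or UACR > 3 mg/mmol. eGFR uses the
  CKD-EPI 2009 creatinine equation without the race coefficient; creatinine
  may be given in mg/dL or µmol/L (÷ 88.4). The ≤ 60 bound is implemented
  *inclusive* exactly as specified upstream, although the usual clinical
  convention is < 60 — a deliberate as-printed choice, flagged here.
* **CVD**: any self-reported heart attack, stroke/TIA, congestive heart
  failure, or angina.
* **MM**: ≥ 2 of the four conditions. `phenotype_cohort()` retains rows aged
  40–60 (inclusive on both ends — reported thresholds like `age >= 54` and
  `age <= 57` presuppose 60 is inside) with all four flags derivable;
  complete-case filtering applies to the condition flags only, while scan
  features keep missing values as an excluded pseudo-level.

## The synthetic generator

Real cohort data of this kind sits behind controlled access, so the package
ships a generator that emulates what the analysis *assumes*, making every
stage testable end to end:

* Feature marginals: age uniform on 40–60; BMI, waist circumference,
  triglycerides and the other lipids and fat depots log-normal; CIMT normal
  truncated at zero; categorical features multinomial. VAT/SCAT are treated
  as unitless positive reals (their source units are ambiguous). Only ranges
  and units matter downstream.
* Two sites with the study's conditions: baseline MM 16.4% (n = 1465) and
  9.7% (n = 1942), ≤ 1% per-cell missingness.
* Ground truth by planting: each row satisfying a planted description has
  its outcome odds multiplied by a known factor. In *outcome mode* the
  planting acts on `mm` directly (for scan tests — the realized odds ratio
  converges to the planted multiplier). In *biomarker mode* it acts on the
  four condition odds; biomarkers are then rendered strictly on the correct
  side of each diagnostic threshold, so phenotyping reproduces the planted
  statuses exactly, and a common logit shift calibrated by root finding
  makes the derived MM rate match the site baseline under conditional
  independence of conditions given the planted multiplier.
* A master seed with named sub-streams per component (`feature:age`,
  `outcome`, `replica17`, ...), so adding a feature never perturbs the
  outcome draw and every pipeline artifact is reproducible from
  (inputs, config, seed).

What the generator does **not** emulate: the covariance structure between
real features (age–BMI, adiposity–lipids correlations), household/geographic
sampling design, and informative missingness. Passing tests therefore show
the *method* behaves as designed (recovers planted truth, is calibrated
under its null, transfers exactly), not that any particular discovered
subset in real data is correct.

## Problem sizes used by the test-suite

The suites validate properties at sizes chosen to make Monte Carlo noise
negligible relative to the tested margins while keeping a laptop run in
minutes: oracle equivalence on 100 random 3-feature instances of n = 100;
planted recovery over 20 cohorts of n = 5,000 (odds multiplier 5, membership
Jaccard ≥ 0.9 required in ≥ 90% of runs); p-value super-uniformity over 200
null cohorts of n = 150 at K = 19; Woolf coverage over 500 simulated 2×2
tables; planted-odds fidelity at n = 50,000 within ±10%.

## Known limitations

* The ascent is a heuristic; global optimality is only guaranteed where the
  exhaustive oracle is feasible.
* $B(S) = \mu |S|$ is the constant-rate expectation; covariate-adjusted
  expectations (e.g. a regression baseline) are out of scope by design.
* The randomization test conditions on the realized features and the
  observed $\mu$; it tests "no subset deviates from the population rate",
  not any causal claim.
* Cross-sectional phenotyping: low eGFR and albuminuria are single
  measurements, not confirmed by follow-up; condition control status is not
  modelled.
* `stats_from_fractions()` is exact only when the supplied fractions are;
  three-decimal inputs limit reconstruction accuracy at n in the thousands.
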