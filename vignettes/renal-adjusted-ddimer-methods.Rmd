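---
title: "Renal function-adapted D-dimer cutoffs: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Renal function-adapted D-dimer cutoffs: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddrenal)
```

## The clinical problem

D-dimer is the standard blood test for ruling out pulmonary embolism (PE) in
emergency-department patients with low-to-intermediate clinical probability:
a value below the cutoff makes CT pulmonary angiography (CTA) unnecessary.
Because D-dimer rises with declining renal function (and with age,
inflammation, malignancy and pregnancy), the conventional 500 µg/l cutoff
loses almost all specificity in patients with impaired kidneys — nearly
every patient with an eGFR below 60 ml/min tests positive, so the rule-out
pathway collapses into CTA-for-everyone exactly in the population where
contrast exposure is most harmful. The remedy examined here is a
*renal-function-adapted* cutoff: within each renal stratum, raise the cutoff
as far as safety permits, where safety means the negative predictive value
(NPV) of the rule "no CTA if D-dimer < cutoff" stays at or above a target
(0.99, i.e. post-test PE probability below 1%).

`ddrenal` implements that analysis end to end: clinical calculators, the
NPV-constrained cutoff search, stratified test-performance metrics,
reclassification and avoided-imaging cost comparison between strategies, and
a synthetic cohort generator for validating the machinery when patient-level
data cannot be shared.

## Clinical calculators

* **eGFR** uses the 2009 CKD-EPI creatinine equation,
  `141 · min(Scr/κ,1)^α · max(Scr/κ,1)^−1.209 · 0.993^Age · 1.018[female] ·
  1.159[black]`, with creatinine converted from µmol/l at 88.42 µmol/l per
  mg/dl. The output is used unrounded and without body-surface-area
  rescaling. Strata are `gte60` (≥ 60 ml/min), `s30_59` (moderate
  impairment) and `lt30` (severe); the boundary values 60 and 30 belong to
  the upper band.
* **Wells score** uses the standard two-level weighting (3 / 3 / 1.5 / 1.5 /
  1.5 / 1 / 1); classes are low (< 2), moderate (2–6), high (> 6), and a
  separate flag marks scores below 6.5, the conventional bound above which
  guidelines send patients directly to CTA without D-dimer testing.
* **YEARS** rules out PE when no item is present and D-dimer < 1000 µg/l,
  or ≥ 1 item and D-dimer < 500 µg/l (strict inequalities).
* **Age-adjusted cutoff** is the conventional rule — 500 µg/l through age
  50, age × 10 µg/l above. The comparator analyses we reproduce name this
  rule without restating it; we adopt the standard definition and flag that
  here.

## The NPV-constrained cutoff search

For records sorted by D-dimer, the NPV of "negative iff ddimer < c" is a
step function that changes only at observed values. The candidate set is
therefore the sorted unique observed D-dimer values, plus one sentinel at
max + 1 µg/l so that "rule out everyone" is expressible. `derive_cutoff()`
returns the **largest** candidate whose point-estimate NPV meets the target:
the largest safe cutoff maximizes rule-outs and hence specificity.
Tie-breaks and degenerate cases:

* a value equal to the cutoff is test-**positive** (the rule-out set is
  strictly below the cutoff);
* candidates with zero negatives have undefined NPV and are infeasible by
  definition — NPV is never silently coerced to 0 or 1;
* if no candidate is feasible the result carries `feasible = FALSE` and the
  smallest candidate (rule out nobody);
* the point estimate, not a confidence bound, is compared against the
  target, matching how such cutoffs are usually tabulated (NPV printed as
  exactly 0.99 at the derived cutoff).

The same search applied within CRP bands (≥ 50 / 100 / 150 mg/l) yields
CRP-adjusted cutoffs at targets 0.99 and 0.95. By default the derivation is
restricted to Wells < 6.5 records; `include_high_wells` lifts that.

## Metrics and intervals

Sensitivity, specificity, PPV, NPV and accuracy come from the standard 2×2
equations with the convention above. The source analyses do not state a CI
method; we default to **Wilson score** intervals (whose degenerate behaviour
at proportions of 0/1 matches printed intervals like "1.0 (CI 1.0–1.0)"
after rounding) with Clopper–Pearson available as a config switch for
sensitivity analysis. Likelihood-ratio CIs use the log method; the AUC —
computed as the Mann–Whitney probability with ties counted ½ — uses the
Hanley–McNeil standard error. Odds ratios use Wald log-scale CIs with the
Haldane–Anscombe 0.5 correction applied only when a zero cell exists.
Every metric with a zero denominator is reported with an explicit
`undefined` marker. All computation is unrounded; rounding happens only at
render time.

## Strategy comparison

Strategies (fixed cutoff, age-adjusted, renal-adjusted per stratum,
refer-all) are first-class objects with a JSON mini-format. The **net
reclassification improvement** is the binary two-category variant — the
decision is dichotomous (CTA vs rule-out), so the continuous NRI does not
apply: NRI = [P(up|PE) − P(down|PE)] + [P(down|no PE) − P(up|no PE)], where
"up" means reclassified negative→positive under the new strategy. Because
the reference strategy behind published NRI values of this kind is often
ambiguous, the pipeline reports all three pairwise comparisons
(age-adjusted vs refer-all, renal-adjusted vs refer-all, renal-adjusted vs
age-adjusted) rather than guessing. **Cost comparison** counts negative
CTAs (scan performed, no PE) under each strategy among Wells < 6.5 records
and multiplies avoided scans by the unit cost (default 488 CHF per CTA, the
aggregate Swiss TARMED tariff); PE cases the new strategy would rule out
are reported as `missed_pe`, never netted away.

## The synthetic cohort generator

No patient-level dataset accompanies the analyses this package
re-implements, so validation runs on synthetic cohorts whose generative
model is the published multivariable regression of ln(D-dimer):

ln(ddimer) = β₀ + 0.012·age − 0.07·female + 0.959·pe + 0.237·malignancy +
0.918·pregnancy − 0.3467·ln(eGFR) + 0.0297·ln(CRP) + ε,  ε ~ N(0, σ²)

with CRP floored at 1 mg/l before the log (ln 0 is undefined). Defaults
encode the stated cohort structure: n = 1369, 53% female, age ~ rounded
truncated normal (mean 66, SD 18.5, support 18–100, matching median 66 and
IQR 54–79), renal strata drawn with probabilities 0.79 / 0.19 / 0.02 and
creatinine rejection-sampled within the stratum (log-normal per stratum,
medians 75 / 130 / 260 µmol/l, capped at 1000 attempts so a misconfigured
distribution fails loudly instead of silently distorting the stratum), CRP
log-normal with median 10 mg/l and ln-SD 1.5 (a typical heavy-tailed ED
distribution that leaves ~3–4% of records above 150 mg/l so the CRP rows
are estimable), PE drawn per Wells class at prevalences 0.02 / 0.36 / 0.54,
and PE location sampled at the reported 19/33/16/32% split.

Two parameters are not identified by published marginals and were
calibrated **once**, by coarse grid search, before any acceptance
measurement, and then frozen as plain config defaults: the intercept
β₀ = 7.60 and residual SD σ = 0.90, chosen so the synthetic median D-dimer
in the ≥ 60 ml/min stratum falls near 1096 µg/l and the stratum IQR ratio
matches 1727/465. Wells item marginals are likewise free parameters chosen
(by exact enumeration over the 2⁷ item patterns) to put ~59% of records in
the low class; items are drawn independently because no joint distribution
is published, and the malignancy item doubles as the malignancy covariate.
The ancestry flag defaults to FALSE throughout (no ancestry distribution is
reported). Cohorts are complete-case and post-exclusion (adults, not
anticoagulated); the CSV reader supports an anticoagulation filter for
testing the exclusion path. All randomness flows through one seeded
Mersenne-Twister stream and the caller's RNG state is restored, so a config
(including its seed) identifies a cohort byte-for-byte.

### What a green test does and does not establish

The generator reproduces the *marginal* structure the analysis assumes —
strata shares, class prevalences, the log-linear D-dimer backbone — and so
validates the machinery: the cutoff search against brute force, CI coverage
of the regression, metric identities. It does **not** reproduce
distributional fine structure of real assay data. The most consequential
gap: in the source data, *no* PE case with eGFR < 60 ml/min had D-dimer
below 500 µg/l (an empirical hard floor, 56 cases), whereas the Gaussian
residual places ~2% of moderate-impairment PE cases below 500 µg/l. With
~40 PE cases per default cohort, roughly half of the seeds contain such a
case, capping the NPV-0.99 cutoff below 500 µg/l. The qualitative claim
"derived moderate-impairment cutoffs exceed 500 µg/l on every seed"
therefore holds only for about 40–50% of seeds under this generative model;
the corresponding acceptance test asserts the claim as stated and is
expected to fail. The published cutoff values themselves (1480 / 1351 µg/l)
are data-realization-dependent and are not reproduction targets.

## Numerical choices and degenerate inputs

* Candidate grids use observed values only — no arbitrary µg/l grid — plus
  the max + 1 sentinel.
* Zero cells, zero denominators and single-class inputs produce explicit
  undefined markers or informative errors, never NaN silence.
* The regression uses a QR solve with pivot-based rank detection; a
  rank-deficient design errors naming the collinear columns. Classical SEs
  are the default (a retrospective chart analysis's default); HC1 robust
  SEs sit behind a flag.
* Univariate correlations are Pearson on untransformed values by default
  (log options exposed); published "univariate linear regression R" values
  are of this kind, and the sign conventions are what the tests check.
* Exclusion order in the pipeline is age, then anticoagulation —
  observationally irrelevant but fixed for log stability.

## Known limitations

* One homogeneous D-dimer assay: the mid-study assay change (reference
  range 243 → 500 µg/l) that real data would carry is not modelled.
* No missing-data mechanism; cohorts are complete-case.
* Wells items are independent in the generator; real items co-occur.
* The severe-impairment stratum holds ~2% of records (~27 patients, ~3 PE
  cases), so its derived cutoffs are extremely unstable — faithfully
  mirroring the instability the source analyses themselves acknowledge.
* NRI is reported without bootstrap CIs, and no multivariable logistic
  PE-risk model is fitted, matching the scope of the analyses reproduced.
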