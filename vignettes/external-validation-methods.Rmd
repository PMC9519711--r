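---
title: "External validation of CSDH prognostic models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{External validation of CSDH prognostic models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdhvalid)
```

## The problem

Chronic subdural hematoma (CSDH) is an encapsulated blood collection
between the dura and the brain, mostly affecting older adults.  Several
prognostic scores and nomograms have been published that predict 30-day
mortality or hematoma recurrence (retreatment by reoperation or
dexamethasone within a fixed window) from admission characteristics such
as age, Glasgow Coma Scale (GCS) category, hematoma volume, septations,
density, and drainage variables.  Before such a model can guide care it
must be validated externally: evaluated, unchanged, on patients from a
different place or time.

`csdhvalid` implements that external-validation workflow as a reusable,
tested pipeline: published models are represented purely as data
(categorization rules, points, and a score-to-risk map), evaluated on a
patient-level cohort, and judged by calibration and discrimination,
under both complete-case and multiple-imputation analyses.

## Models as data

A model definition file carries three things:

* **Predictor rules.**  Either threshold categories over a continuous
  field with *explicit boundary inclusion* — the validated scores
  disagree on this, one dichotomising age as "< 80 vs ≥ 80" and another
  as "≤ 80 vs > 80", so a record aged exactly 80 scores differently
  under the two encodings and the loader refuses any rule set whose
  intervals do not tile the whole axis — or named categories (GCS bands,
  density classes), or a continuous nomogram point axis given as
  anchors, read by piecewise-linear interpolation and clamped at the
  tabulated extremes, which is how one reads a printed nomogram by hand.
* **A risk map.**  Either an exact score-to-probability table (every
  achievable total score must be present; anything else is a load
  error), or a monotone points-to-probability curve interpolated
  linearly.  Probabilities must be strictly inside (0, 1) and monotone
  non-decreasing in the total; both are checked at load time.
* **Metadata.**  The outcome the model predicts, an optional target
  population (the mortality score was developed in patients over 65, so
  it is validated both in all patients and in that subgroup), and a
  citation.

Predicted probabilities are clipped into `[1e-6, 1 - 1e-6]` before the
logit, so every record has a finite linear predictor even under a
degenerate risk map.

The four shipped definition files carry the published models'
categorizations, but their numeric point values and risk tables are
**synthetic placeholders** (the filenames say so): the published numeric
tables live in the original development publications and are not
redistributed here.  The engine is entirely data-driven, so swapping in
transcribed values requires editing a YAML file, not code.

## Performance statistics

Write $p_i$ for the predicted probability, $\ell_i = \operatorname{logit}(p_i)$
for the linear predictor, and $y_i$ for the observed binary outcome.

* **Calibration-in-the-large / intercept** $a$: the maximum-likelihood
  fit of $\operatorname{logit}\Pr(y=1) = a + \ell$ with $\ell$ as a
  fixed offset (slope constrained to 1).  $a < 0$ means predictions were
  on average too high, $a > 0$ too low.
* **Calibration slope** $b$: the fit of
  $\operatorname{logit}\Pr(y=1) = \alpha + b\,\ell$.  $b < 1$ indicates
  overfitted (too extreme) predictions, $b > 1$ underfitted ones.
  Both fits use `stats::glm` with the binomial family — iteratively
  reweighted least squares, which for the canonical logit link is
  exactly Newton–Raphson — with Wald 95% intervals from the information
  matrix.  Non-convergence and runaway coefficients (separation) abort
  with an informative error rather than returning garbage.
* **Concordance index** $C$: the probability that a random event
  patient received a higher prediction than a random non-event patient,
  ties credited 0.5.  Computed in $O(n \log n)$ via midranks; the test
  suite proves exact agreement with an $O(n^2)$ brute-force pair count
  and with `survival::concordance`.  The confidence interval is a
  seeded nonparametric bootstrap (2000 replicates by default),
  percentile method, resampling within events and non-events so every
  replicate is informative.
* **Model-based concordance (mbc)**: the value $C$ would take if every
  $p_i$ were the true event probability,
  $$\mathrm{mbc} = \frac{\sum_{i<j} \max(p_i,p_j)\,(1-\min(p_i,p_j))}
                        {\sum_{i<j} \left[p_i(1-p_j) + p_j(1-p_i)\right]},$$
  with ties taking half the informative mass.  It uses no outcomes, so
  it isolates what the cohort's case-mix heterogeneity alone permits:
  a validation $C$ near the mbc with a slope near 1 means the model's
  coefficients travelled well, while a low mbc means even a perfect
  model could not discriminate in so homogeneous a cohort.  Computed by
  sorted prefix sums in $O(n \log n)$, again proven equal to the
  pairwise definition.
* **Calibration curves**: equal-count risk-decile bins (mean predicted
  vs observed rate per bin) or a lowess smoother (span 0.75, no
  robustness iterations — appropriate for binary outcomes).  When there
  are fewer distinct predictions than bins, the curve falls back to one
  bin per distinct value and flags it.

## Missing data

The analysis mirrors standard practice for registry validations:

* **Complete-case analysis** keeps records with the model's outcome and
  all its predictors observed.
* **Imputation analysis** keeps every record with the outcome observed
  and imputes missing *predictors* by chained equations.  Outcomes are
  never imputed; the imputation engine structurally refuses to alter
  them (they still serve as predictors in the conditional models, with
  a missingness indicator where needed).

The chained-equations engine is implemented in the package: predictive
mean matching (Bayesian parameter draw, 5 nearest donors) for continuous
variables, logistic regression with a posterior parameter draw for
binary ones, and multinomial regression for unordered categories.  Two
details matter:

* **Donor ties.**  With discrete covariates the predicted means are
  heavily tied; donors are randomly permuted before matching so every
  member of a tied run is an equally likely donor.  (A stable sort
  without this step silently collapses the donor pool to a handful of
  records and visibly breaks the coverage of pooled intervals.)
* **Region in every conditional model.**  Hospital region is an
  ordinary column, so a predictor that was never assessed in one region
  is imputed from the other regions' observations; only a variable with
  no observed value anywhere is rejected as unimputable.

Multinomial draws use plug-in (maximum-likelihood) class probabilities
rather than a posterior parameter draw — a documented simplification;
the continuous and binary conditionals are fully proper.  Chains run 10
iterations by default with `m = 10` imputations.

**Pooling** follows Rubin's rules: pooled estimate = mean, total
variance $T = W + (1 + 1/m)B$, t-intervals with Barnard–Rubin degrees of
freedom when the complete-data degrees of freedom are finite.  The
intercept and slope pool on their natural coefficient scale; $C$ pools
on the log-odds scale (bounded statistics pool better unbounded), with
its per-imputation bootstrap variance mapped by the delta method —
a pragmatic combination of bootstrap and Rubin variance, since nothing
more principled is standard; the mbc and mean predicted risk are plain
averages, as they vary only through imputed predictor values.

## The synthetic cohort generator

The registry the package targets is private, so the generator emulates
its published marginals: region mix 10.6/54.7/34.7%, 73.5% male, age
with observed mean 73.0 and SD 12.4 years, hematoma volume with
observed mean 112.6 and SD 54.5 mL, the GCS/density/drainage/treatment
category frequencies, and outcome prevalences 3.9% (30-day mortality),
8.9% (2-month recurrence), 9.5% (3-month recurrence).  Design points:

* Age and volume are truncated normals (18–105 years; positive volume).
  The configured mean/SD are *observed* marginals, so the generator
  moment-matches the underlying normal such that the truncated draw
  reproduces them (naive truncation would shift the volume mean by
  about +2 mL and the age mean by −0.2 years).
* Predictors are drawn independently.  The published table pins no
  joint distribution, and inventing correlations would claim knowledge
  we do not have; this is the generator's main departure from real
  registry data, where age, volume, and density are surely dependent.
  Passing tests therefore demonstrate the *pipeline's* correctness, not
  clinical properties of CSDH.
* Outcomes come from configurable logistic models in standardized age
  and volume plus a few indicators, with deliberately arbitrary
  documented coefficients (true predictor–outcome effects in CSDH are
  not recoverable from published marginals).  Each intercept is solved
  by bisection so the expected prevalence hits its target to ±0.001.
  The 2-month recurrence indicator is carved out of 3-month events with
  probability 155/164 — the ratio of the targeted event counts — so the
  2-month event set always nests inside the 3-month one.
* Missingness defaults mirror the registry's missing-data shares (e.g.
  46.6% for volume, 74.9% for drain type); the two recurrence outcomes
  share one ascertainment mask, and `hematoma_type` is masked together
  with `septations` so the septation-derivation rule (only
  trabecular/membranous types imply septations; unknown types stay
  missing, never a silent "no septations") remains consistent.
  Structural missingness blanks a column for an entire region, which is
  exactly the situation the region-aware imputation handles.

## Numerical and design choices

* Month lengths are conventions: 2 months = 61 days, 3 months = 92
  days, and day-30 death counts as 30-day mortality (inclusive
  boundary, documented since the convention is not universal).
* Bilateral hematomas are excluded once, up front (the validated models
  were developed for unilateral CSDH); the raw table keeps them.
* A global seed deterministically spawns every sub-seed (simulation,
  imputation chains, bootstraps), so one integer reproduces a whole
  run; two runs with the same seed are byte-identical.
* One model's failure (absent predictor column, empty subgroup, too few
  events) marks only its own report cells as failed, with the reason
  recorded; the rest of the run continues.
* Problem sizes in the test suite are chosen for tight Monte-Carlo
  error at interactive runtimes: marginal checks at n = 100,000,
  miscalibration recovery at n = 50,000, imputation coverage with 50
  repetitions of n = 5,000 with m = 10.

## Known limitations

* The shipped model files are placeholders for the published numerics;
  conclusions about the real scores require transcribing their tables.
* Independent predictors understate real case-mix correlation, so mbc
  values on synthetic cohorts do not estimate mbc on registry data.
* The imputation engine covers the variable types this pipeline needs;
  it is not a general mice replacement (no passive imputation, no
  custom predictor matrices, plug-in multinomial draws).
* Competing risks are not modelled: nomogram-based recurrence models
  are consumed as lookups, and death before recurrence is not
  simulated.
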