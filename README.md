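# csdhvalid

External validation of prognostic models for chronic subdural hematoma
(CSDH).

Published risk scores and nomograms promise to predict 30-day mortality
or hematoma recurrence after CSDH treatment, but a model developed in
one hospital's patients routinely falls apart in another's.  This
package implements the full external-validation workflow for such
models, aimed at clinical epidemiologists and methodologists: published
models are loaded as *data* (categorization rules, points, and a
score-to-risk map in a YAML file), evaluated on a patient-level cohort,
and judged by calibration and discrimination under both complete-case
and multiple-imputation analyses.  Because the registry data such
studies use are private, the package ships a synthetic cohort generator
that reproduces registry-style marginal distributions, so the entire
pipeline is testable end to end without any patient data.

## What it computes

For predicted probabilities `p` with linear predictor `lp = logit(p)`
and binary outcomes `y`:

- **Calibration-in-the-large and intercept** `a`: ML fit of
  `logit Pr(y=1) = a + lp` with `lp` as a fixed offset; `a < 0` means
  predictions too high on average, `a > 0` too low.
- **Calibration slope** `b`: ML fit of `logit Pr(y=1) = α + b·lp`;
  `b < 1` flags overfitted (too extreme) predictions, `b > 1`
  underfitted ones.
- **Concordance index** `C` (ties credited 0.5) with a seeded
  bootstrap confidence interval.
- **Model-based concordance** `mbc`: the `C` expected if every
  prediction were exactly right, computed from the predictions alone —
  it isolates what the cohort's case-mix heterogeneity permits.
- **Calibration curves** (risk deciles or a lowess smoother).
- **Multiple imputation** of missing predictors by chained equations
  (predictive mean matching / logistic / multinomial conditionals,
  hospital region in every conditional model, outcomes never imputed)
  with **Rubin's-rules pooling** of all statistics.

## Worked example

Simulate a registry-sized cohort (1760 patients, registry-style
marginals and missingness), then validate the shipped mortality score
on its complete cases:

```r
library(csdhvalid)

cfg    <- synthetic_config(n = 1760, seed = 1)
cohort <- simulate_cohort(cfg)

spec <- read_model_spec(shipped_model_files()[["alford_she_synthetic"]])
cc   <- select_analysis_set(cohort, spec, "complete_case")
pr   <- predict_risk(cc, spec)
validate_predictions(pr$p, cc$mortality_30d, boot = 2000, seed = 2)
#> <csdh_validation> n = 804, events = 31
#>   mean predicted 14.5%; mean observed 3.9%
#>   intercept -1.57 [-1.94, -1.21]
#>   slope     0.53 [0.16, 0.90]
#>   C         0.63 [0.55, 0.72]
#>   mbc       0.72
```

Reading: 804 of 1760 simulated patients have the outcome and all three
predictors observed; the (placeholder) score predicts a 14.5% average
mortality risk against 3.9% observed, hence the strongly negative
calibration intercept (systematic over-prediction); the slope of 0.53
says the score's gradient is about twice as steep as the data support;
discrimination (`C = 0.63`) falls short of what this cohort's case-mix
would allow a perfectly valid model (`mbc = 0.72`).  Note the shipped
model files carry **synthetic placeholder** numerics (the published
point tables are not redistributed), so these numbers exercise the
machinery rather than judge the real scores.

A full run — all four shipped models, complete-case *and* pooled
imputation analyses (`m` imputations, Rubin's rules), optional
per-region rows and subgroup rows for models with a target population —
is one call:

```r
report <- run_validation(cohort, shipped_model_files(),
                         analyses = c("complete_case", "imputation"),
                         m = 10, seed = 1)
render_report(report, "results")   # delimited + human-readable files
```

A thin command-line wrapper with `simulate` / `validate` / `report`
subcommands lives at `inst/cli/csdhvalid.R`.

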