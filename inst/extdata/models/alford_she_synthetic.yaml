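# Subdural Hematoma in the Elderly (SHE) score: 30-day mortality from
# age, admission GCS category, and hematoma volume, developed in patients
# older than 65 years.  Predictor categorizations follow the published
# model (note the boundary: age 80 falls in the UPPER category, "< 80 vs
# >= 80").  The point values and the score-to-probability table below are
# SYNTHETIC PLACEHOLDERS -- the published numeric tables are not
# redistributed with this package; transcribe them from the development
# publication before using this file for a real validation.
name: alford_she
outcome: mortality_30d
target_population: "age > 65"
source: >-
  SHE score (development publication); numeric values here are synthetic
  placeholders.
predictors:
  - field: age
    kind: threshold_category
    categories:
      - label: "<80"
        upper: 80
        upper_inclusive: false
        points: 0
      - label: ">=80"
        lower: 80
        lower_inclusive: true
        points: 1
  - field: gcs_category
    kind: named_category
    categories:
      - level: "13-15"
        points: 0
      - level: "5-12"
        points: 2
      - level: "3-4"
        points: 3
  - field: volume_ml
    kind: threshold_category
    categories:
      - label: "<50"
        upper: 50
        upper_inclusive: false
        points: 0
      - label: ">=50"
        lower: 50
        lower_inclusive: true
        points: 1
risk_map:
  kind: score_table
  table:
    - {score: 0, probability: 0.03}
    - {score: 1, probability: 0.08}
    - {score: 2, probability: 0.20}
    - {score: 3, probability: 0.40}
    - {score: 4, probability: 0.60}
    - {score: 5, probability: 0.80}
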