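# Jack risk-factor score: 2-month hematoma recurrence from age, hematoma
# volume, and septations.  Note the boundary encoding differs from the
# SHE score: age 80 falls in the LOWER category here ("<= 80 vs > 80"),
# and volume is dichotomised at 160 mL ("<= 160 vs > 160").  Point values
# and the score-to-probability table are SYNTHETIC PLACEHOLDERS (see the
# note in alford_she_synthetic.yaml).
name: jack
outcome: recurrence_2m
source: >-
  Jack risk-factor scoring system (development publication); numeric
  values here are synthetic placeholders.
predictors:
  - field: age
    kind: threshold_category
    categories:
      - label: "<=80"
        upper: 80
        upper_inclusive: true
        points: 0
      - label: ">80"
        lower: 80
        lower_inclusive: false
        points: 1
  - field: volume_ml
    kind: threshold_category
    categories:
      - label: "<=160"
        upper: 160
        upper_inclusive: true
        points: 0
      - label: ">160"
        lower: 160
        lower_inclusive: false
        points: 1
  - field: septations
    kind: named_category
    categories:
      - level: "false"
        points: 0
      - level: "true"
        points: 1
risk_map:
  kind: score_table
  table:
    - {score: 0, probability: 0.06}
    - {score: 1, probability: 0.12}
    - {score: 2, probability: 0.24}
    - {score: 3, probability: 0.40}
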