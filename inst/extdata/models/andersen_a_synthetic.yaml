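# Andersen model A (postoperative nomogram): 3-month recurrence from
# hematoma volume, hematoma density, history of hypertension, drainage
# time, drain type, and postoperative surgical complications.  Developed
# with competing-risk regression; consumed here purely as a nomogram:
# each predictor contributes points (continuous volume read off a
# piecewise-linear point axis) and total points map to risk through a
# monotone curve.  All numeric values are SYNTHETIC PLACEHOLDERS (see the
# note in alford_she_synthetic.yaml).
name: andersen_a
outcome: recurrence_3m
source: >-
  Andersen postoperative nomogram (model A); numeric values here are
  synthetic placeholders.
predictors:
  - field: volume_ml
    kind: linear_points
    anchors:
      - {value: 0, points: 0}
      - {value: 50, points: 25}
      - {value: 150, points: 60}
      - {value: 300, points: 100}
  - field: density
    kind: named_category
    categories:
      - {level: homogeneous, points: 0}
      - {level: mixed, points: 20}
      - {level: membranous, points: 35}
      - {level: separated, points: 45}
  - field: hypertension
    kind: named_category
    categories:
      - {level: "false", points: 0}
      - {level: "true", points: 20}
  - field: drainage_time
    kind: named_category
    categories:
      - {level: "1-24h", points: 0}
      - {level: "24-48h", points: 10}
      - {level: ">48h", points: 20}
      - {level: no_drain, points: 40}
  - field: drain_type
    kind: named_category
    categories:
      - {level: subgaleal_subperiosteal, points: 0}
      - {level: subdural, points: 20}
      - {level: no_drain, points: 30}
  - field: postop_complication
    kind: named_category
    categories:
      - {level: "false", points: 0}
      - {level: "true", points: 25}
risk_map:
  kind: nomogram_curve
  table:
    - {points: 0, probability: 0.02}
    - {points: 50, probability: 0.05}
    - {points: 100, probability: 0.10}
    - {points: 150, probability: 0.20}
    - {points: 200, probability: 0.35}
    - {points: 260, probability: 0.55}
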