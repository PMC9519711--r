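# Andersen model B (preoperative nomogram): 3-month recurrence from
# hematoma volume, hematoma density, and history of hypertension only --
# the predictors available before surgery.  Consumed as a nomogram
# lookup, like model A.  All numeric values are SYNTHETIC PLACEHOLDERS
# (see the note in alford_she_synthetic.yaml).
name: andersen_b
outcome: recurrence_3m
source: >-
  Andersen preoperative nomogram (model B); numeric values here are
  synthetic placeholders.
predictors:
  - field: volume_ml
    kind: linear_points
    anchors:
      - {value: 0, points: 0}
      - {value: 50, points: 30}
      - {value: 150, points: 70}
      - {value: 300, points: 100}
  - field: density
    kind: named_category
    categories:
      - {level: homogeneous, points: 0}
      - {level: mixed, points: 25}
      - {level: membranous, points: 40}
      - {level: separated, points: 55}
  - field: hypertension
    kind: named_category
    categories:
      - {level: "false", points: 0}
      - {level: "true", points: 30}
risk_map:
  kind: nomogram_curve
  table:
    - {points: 0, probability: 0.03}
    - {points: 60, probability: 0.08}
    - {points: 120, probability: 0.18}
    - {points: 185, probability: 0.35}
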