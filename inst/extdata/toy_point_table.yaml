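# Toy point table for examples and tests — NOT the published score values.
version: toy-1
age_bands:
  - {lower: 18, upper: 59, points: 0}
  - {lower: 60, upper: 79, points: 5}
  - {lower: 80, upper: Inf, points: 8}
comorbidities:
  - name: heart_failure
    points: 4
    prefixes: [I50]
  - name: chronic_pulmonary_disease
    points: 2
    prefixes: [J44]
surgeries:
  - name: cholecystectomy
    points: 6
    prefixes: [5-511]
  - name: hernia_repair
    points: 1
    prefixes: [5-530]
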