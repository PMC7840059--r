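# Template for the POSPOM point table.
#
# The published point values (age bands, the 15 comorbidity ICD-10 groups and
# the index-surgery categories with their points) are NOT distributed with
# this package: transcribe them from the supplementary material of the
# original score publication (Le Manach et al. 2016) or from your
# institution's adaptation, then validate with
# gpospom::validate_point_table(gpospom::load_point_table("this_file.yaml")).
#
# Conventions: prefixes are matched against normalized codes (uppercase, dots
# stripped); age bands are inclusive on both ends; use `Inf` for the open
# upper end of the last band; points are non-negative integers.
version: FILL-IN provenance, e.g. "S1 transcription YYYY-MM-DD"
age_bands:
  - {lower: 18, upper: FILL-IN, points: FILL-IN}
  # ... further bands, gapless, ending with an open band:
  - {lower: FILL-IN, upper: Inf, points: FILL-IN}
comorbidities:
  - {name: comorbidity_01, points: FILL-IN, prefixes: [FILL-IN]}
  - {name: comorbidity_02, points: FILL-IN, prefixes: [FILL-IN]}
  - {name: comorbidity_03, points: FILL-IN, prefixes: [FILL-IN]}
  - {name: comorbidity_04, points: FILL-IN, prefixes: [FILL-IN]}
  - {name: comorbidity_05, points: FILL-IN, prefixes: [FILL-IN]}
  - {name: comorbidity_06, points: FILL-IN, prefixes: [FILL-IN]}
  - {name: comorbidity_07, points: FILL-IN, prefixes: [FILL-IN]}
  - {name: comorbidity_08, points: FILL-IN, prefixes: [FILL-IN]}
  - {name: comorbidity_09, points: FILL-IN, prefixes: [FILL-IN]}
  - {name: comorbidity_10, points: FILL-IN, prefixes: [FILL-IN]}
  - {name: comorbidity_11, points: FILL-IN, prefixes: [FILL-IN]}
  - {name: comorbidity_12, points: FILL-IN, prefixes: [FILL-IN]}
  - {name: comorbidity_13, points: FILL-IN, prefixes: [FILL-IN]}
  - {name: comorbidity_14, points: FILL-IN, prefixes: [FILL-IN]}
  - {name: comorbidity_15, points: FILL-IN, prefixes: [FILL-IN]}
surgeries:
  # one entry per index-surgery category, OPS prefixes per your mapping of
  # the original procedure categories to the national procedure classification
  - {name: surgery_category_01, points: FILL-IN, prefixes: [FILL-IN]}
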