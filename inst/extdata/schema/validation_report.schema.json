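{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "gpospom/validation_report.schema.json",
  "title": "Validation report",
  "type": "object",
  "required": ["summary", "decomposition", "auc", "brier", "calibration",
               "per_score_mortality"],
  "properties": {
    "summary": {
      "type": "object",
      "required": ["n", "deaths", "mortality_pct", "mortality_ci"],
      "properties": {
        "n": {"type": "integer", "minimum": 1},
        "deaths": {"type": "integer", "minimum": 0},
        "mortality_pct": {"type": "number", "minimum": 0, "maximum": 100},
        "mortality_ci": {
          "type": "object",
          "required": ["lower", "upper"],
          "properties": {
            "lower": {"type": "number", "minimum": 0, "maximum": 100},
            "upper": {"type": "number", "minimum": 0, "maximum": 100}
          }
        },
        "sex_strata": {"type": "array"},
        "sex_stratum_shortfall": {"type": "integer"}
      }
    },
    "attrition": {
      "type": ["object", "null"],
      "required": ["n_input", "n_no_index_procedure", "n_under_18",
                   "n_incomplete", "n_included"]
    },
    "decomposition": {
      "type": "object",
      "required": ["total_points", "comorbidity_points_total",
                   "age_points_total", "surgery_points_total", "shares"]
    },
    "auc": {"type": ["number", "null"], "minimum": 0, "maximum": 1},
    "brier": {"type": "number", "minimum": 0, "maximum": 1},
    "calibration": {
      "type": "object",
      "required": ["slope", "intercept", "points"]
    },
    "per_score_mortality": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["score", "n", "deaths", "mortality_pct"]
      }
    }
  }
}
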