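{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "gpospom/risk_map.schema.json",
  "title": "Score-to-probability risk map",
  "type": "object",
  "required": ["mode"],
  "properties": {
    "mode": {"enum": ["logistic", "table"]},
    "logistic": {
      "type": "object",
      "required": ["intercept", "slope"],
      "properties": {
        "intercept": {"type": "number"},
        "slope": {"type": "number"}
      }
    },
    "table": {
      "type": "object",
      "patternProperties": {
        "^[0-9]+$": {"type": "number", "minimum": 0, "maximum": 1}
      },
      "additionalProperties": false
    }
  },
  "allOf": [
    {
      "if": {"properties": {"mode": {"const": "logistic"}}},
      "then": {"required": ["logistic"]}
    },
    {
      "if": {"properties": {"mode": {"const": "table"}}},
      "then": {"required": ["table"]}
    }
  ]
}
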