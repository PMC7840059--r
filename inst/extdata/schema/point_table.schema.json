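{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "gpospom/point_table.schema.json",
  "title": "POSPOM point table",
  "type": "object",
  "required": ["age_bands", "comorbidities", "surgeries"],
  "properties": {
    "version": {"type": "string"},
    "age_bands": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["lower", "upper", "points"],
        "properties": {
          "lower": {"type": "number", "minimum": 0},
          "upper": {
            "anyOf": [{"type": "number"}, {"type": "string", "pattern": "^[Ii]nf$"}]
          },
          "points": {"type": "integer", "minimum": 0}
        }
      }
    },
    "comorbidities": {"$ref": "#/$defs/group_list"},
    "surgeries": {"$ref": "#/$defs/group_list"}
  },
  "$defs": {
    "group_list": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "points", "prefixes"],
        "properties": {
          "name": {"type": "string", "minLength": 1},
          "points": {"type": "integer", "minimum": 0},
          "prefixes": {
            "type": "array",
            "minItems": 1,
            "items": {"type": "string", "minLength": 1}
          }
        }
      }
    }
  }
}
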