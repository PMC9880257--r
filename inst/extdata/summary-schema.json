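{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "cionaphase analysis summary",
  "type": "object",
  "required": ["schema_version", "n_events"],
  "properties": {
    "schema_version": {"type": "string"},
    "n_events": {"type": "integer", "minimum": 0},
    "circular": {"$ref": "#/definitions/circular"},
    "segments": {
      "type": "array",
      "items": {"$ref": "#/definitions/circular"}
    },
    "laterality": {"enum": ["L", "R", "indeterminate", null]},
    "thresholds": {"type": "object"}
  },
  "definitions": {
    "circular": {
      "type": "object",
      "required": ["n", "R", "p"],
      "properties": {
        "phase_label": {"type": ["string", "null"]},
        "n": {"type": "integer", "minimum": 0},
        "mean_deg": {"type": ["number", "null"]},
        "R": {"type": "number", "minimum": 0, "maximum": 1},
        "p": {"type": "number", "minimum": 0, "maximum": 1}
      }
    }
  }
}
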