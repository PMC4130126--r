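{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "https://example.org/dcida/decision_problem.schema.json",
  "title": "DCIDA decision problem",
  "type": "object",
  "required": ["dcida_spec_version", "title", "options", "attributes"],
  "properties": {
    "dcida_spec_version": { "type": "string" },
    "title": { "type": "string" },
    "narrative": { "type": "string" },
    "options": {
      "type": "array",
      "minItems": 2,
      "items": {
        "type": "object",
        "required": ["id", "label"],
        "properties": {
          "id": { "type": "string", "minLength": 1 },
          "label": { "type": "string" }
        }
      }
    },
    "attributes": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "label", "direction"],
        "properties": {
          "id": { "type": "string", "minLength": 1 },
          "label": { "type": "string" },
          "direction": { "enum": ["benefit", "harm"] },
          "description": { "type": "string" },
          "document_order": { "type": "integer", "minimum": 1 },
          "event_probability": {
            "type": "object",
            "additionalProperties": { "type": "number", "minimum": 0, "maximum": 1 }
          }
        }
      }
    }
  }
}
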