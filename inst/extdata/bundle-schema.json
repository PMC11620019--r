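{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "cypddi dashboard bundle",
  "type": "object",
  "required": ["schema", "rule_id", "cytochrome", "substrate", "relation",
               "perpetrator", "period", "bin", "n_patients", "time_series",
               "sex", "age", "units", "dosage_status"],
  "properties": {
    "schema": {"type": "string"},
    "rule_id": {"type": "integer"},
    "cytochrome": {"type": "string"},
    "substrate": {"type": "string"},
    "relation": {"type": "string", "enum": ["p_inhib", "p_induc", "mutation"]},
    "perpetrator": {"type": "string"},
    "period": {"type": "array", "items": {"type": "string"}},
    "bin": {"type": "string", "enum": ["day", "week", "month"]},
    "n_patients": {"type": "integer"},
    "time_series": {
      "type": "array",
      "items": {"type": "object", "required": ["bin_start", "n_patients"]}
    },
    "sex": {
      "type": "array",
      "items": {"type": "object", "required": ["sex", "n"]}
    },
    "age": {
      "type": "array",
      "items": {"type": "object", "required": ["band", "n"]}
    },
    "units": {
      "type": "array",
      "items": {"type": "object", "required": ["unit", "n_patients"]}
    },
    "dosage_coverage": {"type": "number", "minimum": 0, "maximum": 1},
    "dosage_status": {
      "type": "array",
      "items": {"type": "object", "required": ["status", "n"]}
    }
  }
}
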