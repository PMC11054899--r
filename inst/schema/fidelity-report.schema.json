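{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/platfid/fidelity-report.schema.json",
  "title": "platfid fidelity report",
  "type": "object",
  "required": ["provenance", "summary", "deviations", "rankings", "consensus", "markers"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["package", "version", "mode"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"},
        "mode": {"enum": ["simulation", "paths"]},
        "seed": {"type": ["integer", "null"]},
        "q_threshold": {"type": "number"},
        "deviation_mode": {"enum": ["pergene-sd", "diff-sd", "rms"]},
        "gsva": {"type": "object"},
        "input_digests": {"type": ["object", "null"]}
      }
    },
    "summary": {
      "type": "object",
      "required": ["level", "platform", "mean_deviation", "sem", "n_patients", "rank"],
      "properties": {
        "level": {"type": "array", "items": {"type": "string"}},
        "platform": {"type": "array", "items": {"type": "string"}},
        "mean_deviation": {"type": "array", "items": {"type": "number"}},
        "sem": {"type": "array", "items": {"type": "number"}},
        "n_patients": {"type": "array", "items": {"type": "integer"}},
        "rank": {"type": "array", "items": {"type": "integer"}}
      }
    },
    "deviations": {
      "type": "object",
      "required": ["patient_id", "platform", "level", "raw_deviation", "normalized_deviation"],
      "properties": {
        "patient_id": {"type": "array", "items": {"type": "string"}},
        "platform": {"type": "array", "items": {"type": "string"}},
        "level": {"type": "array", "items": {"type": "string"}},
        "raw_deviation": {"type": "array", "items": {"type": "number", "minimum": 0}},
        "normalized_deviation": {"type": "array", "items": {"type": "number", "minimum": 0}}
      }
    },
    "rankings": {
      "type": "object",
      "additionalProperties": {"type": "array", "items": {"type": "string"}}
    },
    "consensus": {"type": "array", "items": {"type": "string"}},
    "markers": {
      "type": "object",
      "required": ["n_genes", "n_selected", "threshold"],
      "properties": {
        "n_genes": {"type": "integer"},
        "n_selected": {"type": "integer"},
        "n_constant": {"type": "integer"},
        "threshold": {"type": "number"},
        "n_normal": {"type": "integer"},
        "n_tumor": {"type": "integer"}
      }
    },
    "dendrograms": {
      "type": ["object", "null"],
      "additionalProperties": {"type": "string"}
    }
  }
}
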