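{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "coupling_report summary",
  "type": "object",
  "required": ["provenance", "hub_summary", "divergence", "accuracy",
               "per_class", "convergence", "converged"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["config_hash", "seed", "package_version", "timestamp"],
      "properties": {
        "config_hash": {"type": "string"},
        "seed": {"type": "number"},
        "package_version": {"type": "string"},
        "timestamp": {"type": "string"}
      }
    },
    "hub_summary": {"type": "array"},
    "divergence": {"type": "array"},
    "accuracy": {"type": "number"},
    "per_class": {"type": "array"},
    "convergence": {"type": "array"},
    "converged": {"type": "boolean"}
  }
}
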