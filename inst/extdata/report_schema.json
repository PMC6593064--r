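{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "seedshift pipeline report",
  "type": "object",
  "required": ["seed", "stages_run", "results"],
  "properties": {
    "seed": { "type": "integer" },
    "stages_run": {
      "type": "array",
      "items": { "type": "string",
                 "enum": ["simulate", "assoc", "scan", "thermo", "expr"] }
    },
    "results": {
      "type": "object",
      "properties": {
        "assoc": { "type": "object" },
        "scan": { "type": "object" },
        "thermo": { "type": "object" },
        "expr": { "type": "object" }
      }
    }
  }
}
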