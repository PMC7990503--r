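{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "moralcost pipeline configuration",
  "description": "Settings accepted by pipeline_config(); JSON mirror for external tooling.",
  "type": "object",
  "properties": {
    "preset": {"enum": ["full", "test"],
               "description": "full: 4 chains x (2000+1000), 5000 permutations, 4000 PPC reps; test: 2 chains x (400+400), 500 permutations, 200 PPC reps"},
    "models": {"type": "array", "items": {"type": "integer", "minimum": 1, "maximum": 7},
               "description": "utility model ids to fit and compare"},
    "seed": {"type": "integer", "description": "master seed; every stage seed derives from it"},
    "out_dir": {"type": ["string", "null"], "description": "directory for JSON stage reports"},
    "pop_spec": {
      "type": "object",
      "properties": {
        "model_id": {"type": "integer"},
        "n_subjects": {"type": "integer", "minimum": 2},
        "means": {"type": "object", "additionalProperties": {"type": "number"}},
        "sds": {"type": "object", "additionalProperties": {"type": "number", "minimum": 0}},
        "tau": {"type": ["number", "array"], "description": "fixed value in [0,10] or [mean, sd]"}
      }
    },
    "pattern_spec": {
      "type": "object",
      "properties": {
        "n_subjects": {"type": "integer"},
        "n_voxels": {"type": "integer", "minimum": 2},
        "condition_effect": {"type": "number"},
        "shared_signal": {"type": "number"},
        "behavior_coupling": {"type": "number", "minimum": 0, "maximum": 1},
        "noise_sd": {"type": "number", "minimum": 0}
      }
    },
    "mcmc": {
      "type": "object",
      "properties": {
        "chains": {"type": "integer", "minimum": 1},
        "warmup": {"type": "integer"},
        "iter": {"type": "integer"},
        "adapt_delta": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
        "max_depth": {"type": "integer"}
      }
    },
    "n_perm": {"type": "integer", "minimum": 1},
    "ppc_reps": {"type": "integer", "minimum": 1}
  },
  "required": ["preset", "models", "seed"]
}
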