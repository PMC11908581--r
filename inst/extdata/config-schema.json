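{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "chromaqc pipeline configuration",
  "description": "Arguments accepted by pipeline_config(); exactly one of simulate / chromatograms / quality_table must be present.",
  "type": "object",
  "properties": {
    "simulate": {
      "type": "object",
      "properties": {
        "n_compounds": {"type": "integer", "minimum": 1},
        "tier_mixture": {
          "type": "array", "items": {"type": "number", "minimum": 0},
          "minItems": 3, "maxItems": 3
        },
        "sigma": {"type": "number", "exclusiveMinimum": 0},
        "tr_noise_sd": {"type": "number", "minimum": 0}
      },
      "required": ["n_compounds"]
    },
    "quality_table": {
      "type": "string",
      "description": "Path to a quality-table CSV (columns compound_id,sequence,delta_tr,snr,skewness,peak_area,length,sulfur_count,tr,injection_volume)"
    },
    "seed": {"type": "integer"},
    "x": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
    "n_components": {"type": "integer", "minimum": 1},
    "variance_threshold": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
    "k_range": {"type": "array", "items": {"type": "integer", "minimum": 1}},
    "k": {"type": "integer", "minimum": 1},
    "model": {"enum": ["gb", "svr"]},
    "n_estimators": {"type": "array", "items": {"type": "integer"}},
    "test_fraction": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
    "cv_folds": {"type": "integer", "minimum": 2},
    "min_cluster_size": {"type": "integer", "minimum": 1},
    "plots": {"type": "boolean"}
  }
}
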