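{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "aeroscatter run configuration",
  "type": "object",
  "properties": {
    "scenario": {"type": "string", "enum": ["sweep", "compare", "size_ratio"]},
    "mesh_path": {"type": "string", "description": "STL/OBJ/PLY body mesh"},
    "ellipsoid_mm": {
      "type": "array", "items": {"type": "number", "exclusiveMinimum": 0},
      "minItems": 3, "maxItems": 3,
      "description": "FULL axis lengths (anteroposterior, lateral, dorsoventral) in mm"
    },
    "toy_organism": {
      "type": ["object", "boolean"],
      "properties": {
        "wing_span": {"type": "number", "exclusiveMinimum": 0},
        "wing_chord": {"type": "number", "exclusiveMinimum": 0},
        "wing_thickness": {"type": "number", "exclusiveMinimum": 0},
        "wing_sweep_deg": {"type": "number"}
      }
    },
    "material": {"type": "string", "default": "bat_effective"},
    "frequency_hz": {
      "oneOf": [{"type": "number", "exclusiveMinimum": 0},
                {"type": "array", "items": {"type": "number", "exclusiveMinimum": 0}}]
    },
    "plane_tilt_deg": {"type": "number", "default": 0},
    "azimuth_step_deg": {"type": "number", "default": 10,
                         "description": "must divide 360"},
    "spacing_m": {"type": "number", "exclusiveMinimum": 0,
                  "description": "override the lambda/(10|m|) spacing rule"},
    "max_spacing_m": {"type": "number", "exclusiveMinimum": 0},
    "tolerance": {"type": "number", "default": 1e-5},
    "method": {"type": "string", "enum": ["auto", "direct", "fft"]},
    "polarizability_model": {"type": "string", "enum": ["ldr", "cm_rr", "cm"]},
    "unit_scale": {"type": "number", "default": 0.001,
                   "description": "mesh file units -> meters"},
    "partial_voxels": {"type": "boolean", "default": false},
    "emulation": {
      "type": "object",
      "properties": {
        "dynamic_range_limit": {"type": "number", "default": 8},
        "median_halfwidth": {"type": "number", "default": 15},
        "mode": {"type": "string", "enum": ["shv", "plain"]}
      }
    },
    "output_dir": {"type": "string"},
    "seed": {"type": "integer"}
  },
  "anyOf": [
    {"required": ["mesh_path"]},
    {"required": ["ellipsoid_mm"]},
    {"required": ["toy_organism"]}
  ]
}
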