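{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Full-mouth periodontal chart",
  "description": "Normative definition of the JSON chart dialect. Probing depth and recession are integer millimetres; recession is signed, positive when the gingival margin lies apical to the CEJ. Exactly one record per Universal tooth number 1-32.",
  "type": "object",
  "required": ["chart_id", "exam_date", "profile", "teeth"],
  "additionalProperties": false,
  "properties": {
    "chart_id": {"type": "string", "minLength": 1},
    "exam_date": {"type": "string", "format": "date"},
    "profile": {
      "type": "object",
      "required": ["age_years"],
      "additionalProperties": false,
      "properties": {
        "age_years": {"type": "integer", "minimum": 1},
        "smoking_cigarettes_per_day": {"type": "integer", "minimum": 0},
        "has_diabetes": {"type": "boolean"},
        "hba1c_percent": {"type": ["number", "null"], "minimum": 0},
        "systemic_disease_codes": {"type": "array", "items": {"type": "string"}},
        "teeth_lost_to_periodontitis": {"type": "integer", "minimum": 0},
        "history_of_periodontal_treatment": {"type": "boolean"},
        "masticatory_dysfunction": {"type": "boolean"}
      }
    },
    "teeth": {
      "type": "array",
      "minItems": 1,
      "maxItems": 32,
      "items": {
        "type": "object",
        "required": ["tooth_number"],
        "additionalProperties": false,
        "properties": {
          "tooth_number": {"type": "integer", "minimum": 1, "maximum": 32},
          "present": {"type": "boolean"},
          "is_implant": {"type": "boolean"},
          "bone_loss_percent": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
          "furcation_class": {"type": "integer", "minimum": 0, "maximum": 3},
          "mobility_class": {"type": "integer", "minimum": 0, "maximum": 3},
          "flags": {
            "type": "array",
            "items": {
              "enum": ["defective_restoration", "subgingival_margin",
                       "enamel_projection", "root_proximity",
                       "endodontic_involvement", "abscess", "fremitus",
                       "widened_pdl", "progressive_bone_loss",
                       "vertical_defect", "keratinized_tissue_deficiency"]
            }
          },
          "sites": {
            "type": "array",
            "maxItems": 6,
            "items": {
              "type": "object",
              "required": ["site"],
              "additionalProperties": false,
              "properties": {
                "site": {"enum": ["MB", "B", "DB", "ML", "L", "DL"]},
                "pd": {"type": ["integer", "null"], "minimum": 0, "maximum": 20},
                "rec": {"type": ["integer", "null"], "minimum": -5, "maximum": 15},
                "bop": {"type": "boolean"},
                "sup": {"type": "boolean"}
              }
            }
          }
        }
      }
    }
  }
}
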