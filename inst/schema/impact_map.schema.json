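{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "sroikit/impact_map/1.0",
  "title": "SROI impact map",
  "type": "object",
  "required": ["schema_version", "stakeholders", "inputs", "outcomes", "proxies", "indicators"],
  "properties": {
    "schema_version": {"type": "string"},
    "discount_rate": {"type": "number", "minimum": 0, "exclusiveMaximum": 1},
    "currency_table": {
      "type": "object",
      "properties": {"GBP": {"const": 1}},
      "additionalProperties": {"type": "number", "exclusiveMinimum": 0}
    },
    "stakeholders": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": {"type": "string"},
          "label": {"type": "string"},
          "inclusion": {"enum": ["included", "inputs_only", "excluded"]},
          "rationale": {"type": "string"},
          "group": {"enum": ["pwd", "family_caregiver", "staff_caregiver"]}
        }
      }
    },
    "inputs": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["stakeholder_id", "kind", "total_value"],
        "properties": {
          "stakeholder_id": {"type": "string"},
          "kind": {"enum": ["cash", "in_kind", "time"]},
          "description": {"type": "string"},
          "hours_per_unit": {"type": "number", "minimum": 0},
          "unit_count": {"type": "number", "minimum": 0},
          "hourly_rate": {"type": "number", "minimum": 0},
          "total_value": {"type": "number", "minimum": 0}
        }
      }
    },
    "indicators": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "instrument"],
        "properties": {
          "id": {"type": "string"},
          "instrument": {"type": "string"},
          "direction": {"enum": ["higher_is_better", "lower_is_better"]},
          "rule": {"enum": ["strict_improvement", "maintain_or_increase", "endorsed_at_followup"]},
          "baseline_time": {"type": "string"},
          "followup_time": {"type": "string"},
          "score_min": {"type": "number"},
          "score_max": {"type": "number"}
        }
      }
    },
    "proxies": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["code", "annual_value"],
        "properties": {
          "code": {"type": "string"},
          "label": {"type": "string"},
          "annual_value": {"type": "number", "exclusiveMinimum": 0},
          "source": {"type": "string"}
        }
      }
    },
    "outcomes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "stakeholder_id", "indicator_id", "quantity", "denominator", "proxy_code"],
        "properties": {
          "id": {"type": "string"},
          "stakeholder_id": {"type": "string"},
          "description": {"type": "string"},
          "indicator_id": {"type": "string"},
          "quantity": {"type": "number", "minimum": 0},
          "denominator": {"type": "number", "minimum": 0},
          "duration_years": {"type": "integer", "minimum": 1},
          "proxy_code": {"type": "string"},
          "adjustments": {
            "type": "object",
            "properties": {
              "multiplier": {"type": "number", "minimum": 0, "maximum": 1},
              "deadweight": {"type": "number", "minimum": 0, "maximum": 1},
              "displacement": {"type": "number", "minimum": 0, "maximum": 1},
              "attribution": {"type": "number", "minimum": 0, "maximum": 1},
              "drop_off": {"type": "number", "minimum": 0, "maximum": 1}
            }
          }
        }
      }
    },
    "residual": {
      "type": "object",
      "required": ["value"],
      "properties": {
        "value": {"type": "number"},
        "duration_years": {"type": "integer", "minimum": 1},
        "drop_off": {"type": "number", "minimum": 0, "maximum": 1},
        "note": {"type": "string"}
      }
    }
  }
}
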