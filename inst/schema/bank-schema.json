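{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "matrixbank item-bank descriptor",
  "type": "object",
  "required": ["format", "version", "config", "items"],
  "properties": {
    "format": {"const": "matrixbank-bank"},
    "version": {"type": "integer"},
    "config": {
      "type": "object",
      "required": ["items_per_rule_count", "n_test_sets",
                   "set_composition", "anchor_composition", "n_practice",
                   "master_seed"],
      "properties": {
        "items_per_rule_count": {
          "type": "object",
          "additionalProperties": {"type": "integer", "minimum": 1}
        },
        "n_test_sets": {"type": "integer", "minimum": 1},
        "set_composition": {
          "type": "object",
          "additionalProperties": {"type": "integer", "minimum": 1}
        },
        "anchor_composition": {
          "type": "object",
          "additionalProperties": {"type": "integer", "minimum": 1}
        },
        "n_practice": {"type": "integer", "minimum": 0},
        "master_seed": {"type": "integer"}
      }
    },
    "items": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["item_id", "cells", "rules", "rule_count", "seed"],
        "properties": {
          "item_id": {"type": "string"},
          "cells": {
            "type": "array",
            "minItems": 9,
            "maxItems": 9,
            "items": {
              "type": "array",
              "items": {"type": "integer", "minimum": 0, "maximum": 19}
            }
          },
          "rules": {
            "type": "array",
            "minItems": 1,
            "maxItems": 5,
            "items": {
              "type": "object",
              "required": ["kind", "family"],
              "properties": {
                "kind": {"enum": ["ADD", "SUB", "DIS", "INT", "ROT",
                                  "COM"]},
                "family": {"type": "integer", "minimum": 0, "maximum": 4},
                "direction": {"enum": ["CW", "CCW"]},
                "required_set": {
                  "type": "array",
                  "minItems": 1,
                  "items": {"type": "integer", "minimum": 0, "maximum": 19}
                }
              }
            }
          },
          "rule_count": {"type": "integer", "minimum": 1, "maximum": 5},
          "is_anchor": {"type": "boolean"},
          "is_practice": {"type": "boolean"},
          "seed": {"type": "integer"}
        }
      }
    },
    "forms": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["form_id", "test_set_item_ids", "anchor_item_ids",
                     "presentation_order"],
        "properties": {
          "form_id": {"type": "string"},
          "test_set_item_ids": {"type": "array",
                                "items": {"type": "string"}},
          "anchor_item_ids": {"type": "array",
                              "items": {"type": "string"}},
          "practice_item_ids": {"type": "array",
                                "items": {"type": "string"}},
          "presentation_order": {"type": "array",
                                 "items": {"type": "string"}}
        }
      }
    }
  }
}
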