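{
  "type": "object",
  "required": {
    "config": {
      "type": "object",
      "required": {
        "experiment": {"type": "number"},
        "n_boot": {"type": "number"},
        "seed": {"type": "number"}
      }
    },
    "exclusions": {
      "type": "object",
      "required": {
        "n_input": {"type": "number"},
        "n_fixation_break": {"type": "number"},
        "n_block_rule": {"type": "number"},
        "n_kept": {"type": "number"}
      }
    },
    "aoc": {
      "type": "object",
      "required": {
        "per_subject": {
          "type": "table",
          "columns": ["subject", "ag_single_top", "ag_single_bottom",
                      "ag_dual_top", "ag_dual_bottom", "dist_serial",
                      "dist_fixed_capacity", "dist_independent", "p_top_hat"]
        },
        "model_tests": {
          "type": "object",
          "required": {
            "serial": {
              "type": "object",
              "required": {
                "mean_diff": {"type": "number"},
                "t": {"type": "number"},
                "df": {"type": "number"},
                "p": {"type": "number"},
                "ci_low": {"type": "number"},
                "ci_high": {"type": "number"},
                "bf": {"type": "number"}
              }
            },
            "fixed_capacity": {"type": "object", "required": {}},
            "independent": {"type": "object", "required": {}}
          }
        },
        "p_top": {
          "type": "object",
          "required": {
            "mean": {"type": "number"},
            "sem": {"type": "number"}
          }
        },
        "side_cue_interaction": {
          "type": "object",
          "required": {
            "F": {"type": "number"},
            "df1": {"type": "number"},
            "df2": {"type": "number"},
            "p": {"type": "number"}
          }
        }
      }
    },
    "tradeoff": {
      "type": "object",
      "required": {
        "per_subject": {
          "type": "table",
          "columns": ["subject", "ag_other_incorrect", "ag_other_correct",
                      "difference", "flagged"]
        }
      }
    },
    "congruency": {
      "type": "object",
      "required": {
        "per_subject": {
          "type": "table",
          "columns": ["subject", "cue_type", "congruency", "ag", "flagged"]
        }
      }
    },
    "response_order": {
      "type": "object",
      "required": {
        "per_subject": {
          "type": "table",
          "columns": ["subject", "ag_first", "ag_second", "difference"]
        }
      }
    }
  }
}
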