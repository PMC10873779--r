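{
  "version": "1.0",
  "description": "Operation whitelist and message payload schemas for hub <-> site exchanges. Any op_name not listed here is rejected; any listed op with a missing required payload field is rejected.",
  "operations": {
    "summarize": {
      "direction": "hub_to_site",
      "required": ["selector", "k", "exchange_id"],
      "response": "summary_result"
    },
    "summary_result": {
      "direction": "site_to_hub",
      "required": ["summary", "exchange_id"]
    },
    "breakdown": {
      "direction": "hub_to_site",
      "required": ["selector", "partition", "k", "exchange_id"],
      "response": "breakdown_result"
    },
    "breakdown_result": {
      "direction": "site_to_hub",
      "required": ["breakdown", "exchange_id"]
    },
    "sufficient_statistics": {
      "direction": "hub_to_site",
      "required": ["selector", "k", "exchange_id"],
      "response": "sufficient_statistics_result"
    },
    "sufficient_statistics_result": {
      "direction": "site_to_hub",
      "required": ["stats", "exchange_id"]
    },
    "train_round": {
      "direction": "hub_to_site",
      "required": ["weights", "epochs", "config", "exchange_id"],
      "response": "site_update"
    },
    "site_update": {
      "direction": "site_to_hub",
      "required": ["update", "exchange_id"]
    },
    "evaluate": {
      "direction": "hub_to_site",
      "required": ["weights", "split", "exchange_id"],
      "response": "evaluation_result"
    },
    "evaluation_result": {
      "direction": "site_to_hub",
      "required": ["metrics", "exchange_id"]
    }
  }
}
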