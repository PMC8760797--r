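{
  "description": "Default SIRS criterion thresholds (classic four-criterion rule).",
  "temp_high": 38, "temp_low": 36,
  "hr": 90,
  "rr": 20, "paco2": 32,
  "wbc_high": 12, "wbc_low": 4, "bands": 10
}
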