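{
  "outpatient": 170,
  "emergency": 160,
  "inpatient": 650,
  "currency": "USD_2023",
  "hkd_per_usd": 7.85,
  "note": "synthetic stand-in for the published charge schedule"
}
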