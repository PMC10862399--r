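{
  "entrants_2023_baseline": 9147,
  "entrants_2023_pandemic": 11397,
  "cumulative_deaths": 899,
  "cumulative_cost_allcause_usd": 309400000,
  "cumulative_cost_psychiatric_usd": 58400000,
  "life_years": {
    "all": 85495,
    "trd": 12326,
    "comorbid": 14196
  },
  "qalys": {
    "all": 60213,
    "trd": 6491,
    "comorbid": 7748
  },
  "annual_cost_allcause_first_musd": 39.5,
  "annual_cost_allcause_last_musd": 24.5,
  "annual_cost_psychiatric_first_musd": 6.5,
  "annual_cost_psychiatric_last_musd": 5.1,
  "note": "headline estimates reported by the published Hong Kong projection study; inputs for derived-ratio benchmarking"
}
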