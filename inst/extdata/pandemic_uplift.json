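{
  "uniform_2023": 1.25,
  "open_2019_2022": 1.33,
  "age_specific_2023": {
    "10-24": 1.443086,
    "25-40": 1.324929,
    "41-65": 1.21662,
    ">65": 1.098463
  }
}
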