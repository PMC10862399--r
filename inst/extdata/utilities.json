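{
  "NTRD": 0.8,
  "TRD": 0.6,
  "low_intensity": 0.85,
  "comorbid_decrement": 0.17,
  "note": "synthetic placeholder utilities; replace with literature values"
}
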