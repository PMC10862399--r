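"year","new_patients"
2014,8397
2015,8455
2016,8544
2017,8601
2018,8688
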