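"age_group","rate_per_10000"
"10-14",12.3256
"15-19",12.3256
"20-24",12.3256
"25-29",15
"30-34",15
"35-39",15
"40-44",21.7188
"45-49",21.7188
"50-54",21.7188
"55-59",21.7188
"60-64",21.7188
"65-69",7.2125
"70-74",7.2125
"75-79",7.2125
"80-84",7.2125
"85+",7.2125
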