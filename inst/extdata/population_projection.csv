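"year","age_group","population"
2014,"10-14",229429
2014,"15-19",247078
2014,"20-24",282374
2014,"25-29",364734
2014,"30-34",400030
2014,"35-39",411796
2014,"40-44",435327
2014,"45-49",423562
2014,"50-54",447093
2014,"55-59",482390
2014,"60-64",470624
2014,"65-69",435327
2014,"70-74",376499
2014,"75-79",270609
2014,"80-84",200015
2014,"85+",405913
2015,"10-14",230347
2015,"15-19",248066
2015,"20-24",283504
2015,"25-29",366192
2015,"30-34",401630
2015,"35-39",413443
2015,"40-44",437068
2015,"45-49",425256
2015,"50-54",448881
2015,"55-59",484319
2015,"60-64",472506
2015,"65-69",437068
2015,"70-74",378005
2015,"75-79",271691
2015,"80-84",200815
2015,"85+",407537
2016,"10-14",231268
2016,"15-19",249058
2016,"20-24",284638
2016,"25-29",367657
2016,"30-34",403237
2016,"35-39",415097
2016,"40-44",438817
2016,"45-49",426957
2016,"50-54",450677
2016,"55-59",486256
2016,"60-64",474396
2016,"65-69",438817
2016,"70-74",379517
2016,"75-79",272778
2016,"80-84",201618
2016,"85+",409167
2017,"10-14",232193
2017,"15-19",250054
2017,"20-24",285776
2017,"25-29",369128
2017,"30-34",404850
2017,"35-39",416757
2017,"40-44",440572
2017,"45-49",428665
2017,"50-54",452479
2017,"55-59",488201
2017,"60-64",476294
2017,"65-69",440572
2017,"70-74",381035
2017,"75-79",273869
2017,"80-84",202425
2017,"85+",410804
2018,"10-14",233122
2018,"15-19",251055
2018,"20-24",286920
2018,"25-29",370604
2018,"30-34",406469
2018,"35-39",418424
2018,"40-44",442334
2018,"45-49",430379
2018,"50-54",454289
2018,"55-59",490154
2018,"60-64",478199
2018,"65-69",442334
2018,"70-74",382559
2018,"75-79",274965
2018,"80-84",203235
2018,"85+",412447
2019,"10-14",234055
2019,"15-19",252059
2019,"20-24",288067
2019,"25-29",372087
2019,"30-34",408095
2019,"35-39",420098
2019,"40-44",444104
2019,"45-49",432101
2019,"50-54",456106
2019,"55-59",492115
2019,"60-64",480112
2019,"65-69",444104
2019,"70-74",384090
2019,"75-79",276064
2019,"80-84",204048
2019,"85+",414097
2020,"10-14",234991
2020,"15-19",253067
2020,"20-24",289219
2020,"25-29",373575
2020,"30-34",409728
2020,"35-39",421778
2020,"40-44",445880
2020,"45-49",433829
2020,"50-54",457931
2020,"55-59",494083
2020,"60-64",482032
2020,"65-69",445880
2020,"70-74",385626
2020,"75-79",277169
2020,"80-84",204864
2020,"85+",415753
2021,"10-14",235931
2021,"15-19",254079
2021,"20-24",290376
2021,"25-29",375069
2021,"30-34",411366
2021,"35-39",423466
2021,"40-44",447664
2021,"45-49",435565
2021,"50-54",459763
2021,"55-59",496060
2021,"60-64",483961
2021,"65-69",447664
2021,"70-74",387168
2021,"75-79",278277
2021,"80-84",205683
2021,"85+",417416
2022,"10-14",236875
2022,"15-19",255096
2022,"20-24",291538
2022,"25-29",376570
2022,"30-34",413012
2022,"35-39",425159
2022,"40-44",449454
2022,"45-49",437307
2022,"50-54",461602
2022,"55-59",498044
2022,"60-64",485896
2022,"65-69",449454
2022,"70-74",388717
2022,"75-79",279390
2022,"80-84",206506
2022,"85+",419086
2023,"10-14",237822
2023,"15-19",256116
2023,"20-24",292704
2023,"25-29",378076
2023,"30-34",414664
2023,"35-39",426860
2023,"40-44",451252
2023,"45-49",439056
2023,"50-54",463448
2023,"55-59",500036
2023,"60-64",487840
2023,"65-69",451252
2023,"70-74",390272
2023,"75-79",280508
2023,"80-84",207332
2023,"85+",420762
2024,"10-14",238773
2024,"15-19",257140
2024,"20-24",293875
2024,"25-29",379588
2024,"30-34",416323
2024,"35-39",428567
2024,"40-44",453057
2024,"45-49",440812
2024,"50-54",465302
2024,"55-59",502036
2024,"60-64",489791
2024,"65-69",453057
2024,"70-74",391833
2024,"75-79",281630
2024,"80-84",208161
2024,"85+",422445
2025,"10-14",239728
2025,"15-19",258169
2025,"20-24",295050
2025,"25-29",381107
2025,"30-34",417988
2025,"35-39",430282
2025,"40-44",454869
2025,"45-49",442575
2025,"50-54",467163
2025,"55-59",504044
2025,"60-64",491751
2025,"65-69",454869
2025,"70-74",393400
2025,"75-79",282757
2025,"80-84",208994
2025,"85+",424135
2026,"10-14",240687
2026,"15-19",259202
2026,"20-24",296231
2026,"25-29",382631
2026,"30-34",419660
2026,"35-39",432003
2026,"40-44",456689
2026,"45-49",444346
2026,"50-54",469032
2026,"55-59",506060
2026,"60-64",493718
2026,"65-69",456689
2026,"70-74",394974
2026,"75-79",283888
2026,"80-84",209830
2026,"85+",425831
2027,"10-14",241650
2027,"15-19",260239
2027,"20-24",297415
2027,"25-29",384162
2027,"30-34",421339
2027,"35-39",433731
2027,"40-44",458515
2027,"45-49",446123
2027,"50-54",470908
2027,"55-59",508085
2027,"60-64",495692
2027,"65-69",458515
2027,"70-74",396554
2027,"75-79",285023
2027,"80-84",210669
2027,"85+",427535
2028,"10-14",242617
2028,"15-19",261279
2028,"20-24",298605
2028,"25-29",385698
2028,"30-34",423024
2028,"35-39",435466
2028,"40-44",460350
2028,"45-49",447908
2028,"50-54",472791
2028,"55-59",510117
2028,"60-64",497675
2028,"65-69",460350
2028,"70-74",398140
2028,"75-79",286163
2028,"80-84",211512
2028,"85+",429245
2029,"10-14",243587
2029,"15-19",262325
2029,"20-24",299800
2029,"25-29",387241
2029,"30-34",424716
2029,"35-39",437208
2029,"40-44",462191
2029,"45-49",449699
2029,"50-54",474683
2029,"55-59",512158
2029,"60-64",499666
2029,"65-69",462191
2029,"70-74",399733
2029,"75-79",287308
2029,"80-84",212358
2029,"85+",430962
2030,"10-14",244561
2030,"15-19",263374
2030,"20-24",300999
2030,"25-29",388790
2030,"30-34",426415
2030,"35-39",438956
2030,"40-44",464040
2030,"45-49",451498
2030,"50-54",476581
2030,"55-59",514206
2030,"60-64",501665
2030,"65-69",464040
2030,"70-74",401332
2030,"75-79",288457
2030,"80-84",213207
2030,"85+",432686
2031,"10-14",245540
2031,"15-19",264427
2031,"20-24",302203
2031,"25-29",390345
2031,"30-34",428121
2031,"35-39",440712
2031,"40-44",465896
2031,"45-49",453304
2031,"50-54",478488
2031,"55-59",516263
2031,"60-64",503671
2031,"65-69",465896
2031,"70-74",402937
2031,"75-79",289611
2031,"80-84",214060
2031,"85+",434416
2032,"10-14",246522
2032,"15-19",265485
2032,"20-24",303412
2032,"25-29",391907
2032,"30-34",429833
2032,"35-39",442475
2032,"40-44",467759
2032,"45-49",455117
2032,"50-54",480402
2032,"55-59",518328
2032,"60-64",505686
2032,"65-69",467759
2032,"70-74",404549
2032,"75-79",290769
2032,"80-84",214916
2032,"85+",436154
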