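# Band mean intakes (grams pure ethanol/day), CALIBRATED by inverting the
# dose-response mortality curve against the published band-level relative
# risks of death (target_rr); larger root of the J-curve taken so intake is
# monotone in band severity. Not observed data. fixtures: nl-2009.1
"gender","band","target_rr","mean_intake"
"men","abstinent",1,0
"men","moderate",0.86,89.490746
"men","heavy",0.95,128.468881
"men","hazardous",0.99,143.481147
"men","harmful",1.1,180.257689
"men","dependence",1.36,250.519844
"women","abstinent",1,0
"women","moderate",0.96,84.992282
"women","heavy",0.99,98.948174
"women","hazardous",1.05,124.258499
"women","harmful",1.12,150.785477
"women","dependence",1.28,203.456168
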