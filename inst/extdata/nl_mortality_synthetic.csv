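# SYNTHETIC gender x age mortality/life-expectancy table: Gompertz hazard
# rate(age) = exp(level + slope*age), level men -9.8 / women -10.4, slope
# men 0.085 / women 0.088, life table closed at age 100. Parameters chosen
# to mimic a Dutch 2009 period life table; NOT observed national
# statistics. fixtures: nl-2009.1
"gender","age","rate","life_expectancy"
"men",18,0.00025608529,61.387116
"men",19,0.00027880443,60.402841
"men",20,0.00030353914,59.419686
"men",21,0.00033046824,58.437728
"men",22,0.00035978641,57.457046
"men",23,0.00039170561,56.477726
"men",24,0.00042645658,55.499857
"men",25,0.00046429056,54.523535
"men",26,0.00050548105,53.548862
"men",27,0.00055032585,52.575943
"men",28,0.00059914915,51.604893
"men",29,0.0006523039,50.635831
"men",30,0.00071017439,49.668882
"men",31,0.00077317898,48.704181
"men",32,0.00084177315,47.741867
"men",33,0.00091645279,46.782089
"men",34,0.0009977578,45.825002
"men",35,0.0010862759,44.87077
"men",36,0.0011826472,43.919565
"men",37,0.0012875681,42.971568
"men",38,0.0014017974,42.026968
"men",39,0.0015261608,41.085964
"men",40,0.0016615573,40.148763
"men",41,0.0018089658,39.215584
"men",42,0.0019694519,38.286652
"men",43,0.0021441759,37.362205
"men",44,0.0023344009,36.442488
"men",45,0.0025415021,35.527758
"men",46,0.0027669767,34.618282
"men",47,0.0030124548,33.714336
"men",48,0.0032797109,32.816206
"men",49,0.0035706772,31.924188
"men",50,0.0038874572,31.038587
"men",51,0.004232341,30.159719
"men",52,0.0046078219,29.287908
"men",53,0.0050166144,28.423486
"men",54,0.0054616737,27.566795
"men",55,0.0059462174,26.718182
"men",56,0.0064737483,25.878005
"men",57,0.0070480803,25.046624
"men",58,0.0076733653,24.224408
"men",59,0.0083541237,23.411728
"men",60,0.0090952771,22.60896
"men",61,0.0099021834,21.816482
"men",62,0.010780676,21.034674
"men",63,0.011737106,20.263913
"men",64,0.012778388,19.504577
"men",65,0.013912049,18.757041
"men",66,0.015146285,18.021671
"men",67,0.016490019,17.29883
"men",68,0.017952965,16.588871
"men",69,0.019545699,15.892135
"women",18,0.00014834054,65.589313
"women",19,0.0001619861,64.599044
"women",20,0.0001768869,63.60951
"women",21,0.0001931584,62.620763
"women",22,0.00021092667,61.632862
"women",23,0.00023032942,60.645864
"women",24,0.00025151699,59.659836
"women",25,0.00027465357,58.674845
"women",26,0.00029991844,57.690965
"women",27,0.00032750737,56.708273
"women",28,0.00035763416,55.726851
"women",29,0.00039053225,54.746788
"women",30,0.00042645658,53.768177
"women",31,0.00046568552,52.791116
"women",32,0.00050852306,51.815712
"women",33,0.00055530114,50.842075
"women",34,0.00060638225,49.870323
"women",35,0.00066216221,48.900582
"women",36,0.00072307327,47.932984
"women",37,0.00078958742,46.967668
"women",38,0.00086222009,46.004782
"women",39,0.00094153409,45.044483
"women",40,0.001028144,44.086934
"women",41,0.0011227211,43.132308
"women",42,0.0012259981,42.180788
"women",43,0.0013387754,41.232565
"women",44,0.0014619268,40.28784
"women",45,0.0015964067,39.346824
"women",46,0.0017432571,38.409738
"women",47,0.0019036161,37.476813
"women",48,0.0020787262,36.548291
"women",49,0.0022699443,35.624423
"women",50,0.0024787522,34.705472
"women",51,0.0027067679,33.791712
"women",52,0.0029557584,32.883427
"women",53,0.0032276531,31.98091
"women",54,0.0035245588,31.084468
"women",55,0.0038487764,30.194414
"women",56,0.0042028181,29.311075
"women",57,0.0045894275,28.434784
"women",58,0.0050116003,27.565885
"women",59,0.005472608,26.70473
"women",60,0.0059760229,25.851679
"women",61,0.006525746,25.007098
"women",62,0.0071260371,24.17136
"women",63,0.0077815479,23.344842
"women",64,0.0084973579,22.527926
"women",65,0.0092790139,21.720994
"women",66,0.010132573,20.924431
"women",67,0.011064649,20.13862
"women",68,0.012082466,19.36394
"women",69,0.013193909,18.600765
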