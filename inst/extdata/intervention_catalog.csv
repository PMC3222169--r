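# Intervention catalog, Netherlands, 2009 euros. Per-participant full
# economic cost (point, uncertainty range) and effect size d (95% CI);
# costs keyed on (disorder, intervention). intake_reduction is the assumed
# pre-post fractional reduction in pure-alcohol intake. fixtures: nl-2009.1
disorder,intervention,cost,cost_low,cost_high,d,d_low,d_high,intake_reduction
heavy,brief_face_to_face,58,52,75,0.26,0.20,0.32,0.20
heavy,online_brief,10,9,10,0.19,-0.02,0.40,0.20
hazardous,brief_face_to_face,58,52,75,0.32,0.23,0.42,0.20
hazardous,online_brief,10,9,10,0.19,-0.02,0.40,0.20
hazardous,behavioral,2024,1702,2550,0.34,0.12,0.56,0.20
hazardous,online_self_help,207,198,224,0.31,-0.69,1.30,0.20
harmful,behavioral,2024,1702,2550,0.34,0.12,0.56,0.20
harmful,online_self_help,207,198,224,0.31,-0.69,1.30,0.20
harmful,online_therapist_led,764,227,1451,0.58,0.29,0.88,0.20
harmful,detox_acamprosate,1800,1620,2232,0.21,0.14,0.29,0.20
harmful,aftercare_aa,500,250,750,0.28,0.20,0.37,0.20
dependence,behavioral,2024,1702,2550,0.32,0.05,0.59,0.20
dependence,online_therapist_led,1276,979,1408,0.59,0.30,0.90,0.20
dependence,detox_acamprosate,1800,1620,2232,0.21,0.14,0.29,0.20
dependence,aftercare_aa,500,250,750,0.28,0.20,0.37,0.20
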