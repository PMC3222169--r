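# Modelled Dutch scenarios: coverage per (disorder, intervention), stored
# as fractions. base_case = current care without eHealth; alternative_1 =
# eHealth added; alternative_2 = face-to-face 50% substituted by eHealth.
# Adherence left blank = package default 0.50. fixtures: nl-2009.1
scenario,disorder,intervention,coverage
base_case,heavy,brief_face_to_face,0.10
base_case,hazardous,brief_face_to_face,0.10
base_case,hazardous,behavioral,0.06
base_case,harmful,behavioral,0.09
base_case,harmful,detox_acamprosate,0.05
base_case,harmful,aftercare_aa,0.05
base_case,dependence,behavioral,0.05
base_case,dependence,detox_acamprosate,0.05
base_case,dependence,aftercare_aa,0.05
alternative_1,heavy,brief_face_to_face,0.10
alternative_1,heavy,online_brief,0.05
alternative_1,hazardous,brief_face_to_face,0.10
alternative_1,hazardous,online_brief,0.05
alternative_1,hazardous,behavioral,0.06
alternative_1,hazardous,online_self_help,0.06
alternative_1,harmful,behavioral,0.09
alternative_1,harmful,online_self_help,0.09
alternative_1,harmful,online_therapist_led,0.09
alternative_1,harmful,detox_acamprosate,0.05
alternative_1,harmful,aftercare_aa,0.05
alternative_1,dependence,behavioral,0.05
alternative_1,dependence,online_therapist_led,0.05
alternative_1,dependence,detox_acamprosate,0.05
alternative_1,dependence,aftercare_aa,0.05
alternative_2,heavy,brief_face_to_face,0.05
alternative_2,heavy,online_brief,0.05
alternative_2,hazardous,brief_face_to_face,0.05
alternative_2,hazardous,online_brief,0.05
alternative_2,hazardous,behavioral,0.03
alternative_2,hazardous,online_self_help,0.03
alternative_2,harmful,behavioral,0.03
alternative_2,harmful,online_self_help,0.03
alternative_2,harmful,online_therapist_led,0.03
alternative_2,harmful,detox_acamprosate,0.05
alternative_2,harmful,aftercare_aa,0.05
alternative_2,dependence,behavioral,0.025
alternative_2,dependence,online_therapist_led,0.025
alternative_2,dependence,detox_acamprosate,0.05
alternative_2,dependence,aftercare_aa,0.05
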