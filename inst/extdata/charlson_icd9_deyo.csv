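condition,weight,supersedes,prefixes
myocardial_infarction,1,,410;412
congestive_heart_failure,1,,428
peripheral_vascular_disease,1,,441;4439;7854;V434
cerebrovascular_disease,1,,430;431;432;433;434;435;436;437;438
dementia,1,,290
chronic_pulmonary_disease,1,,490;491;492;493;494;495;496;500;501;502;503;504;505;5064
rheumatologic_disease,1,,7100;7101;7104;7140;7141;7142;71481;725
peptic_ulcer_disease,1,,531;532;533;534
mild_liver_disease,1,,5712;5714;5715;5716
diabetes,1,,2500;2501;2502;2503;2507
diabetes_with_complications,2,diabetes,2504;2505;2506
hemiplegia_paraplegia,2,,342;3441
renal_disease,2,,582;5830;5831;5832;5833;5834;5835;5836;5837;585;586;5880
any_malignancy,2,,140;141;142;143;144;145;146;147;148;149;150;151;152;153;154;155;156;157;158;159;160;161;162;163;164;165;170;171;172;174;175;176;179;180;181;182;183;184;185;186;187;188;189;190;191;192;193;194;195;200;201;202;203;204;205;206;207;208
moderate_severe_liver_disease,3,mild_liver_disease,4560;4561;4562;5722;5723;5724;5725;5726;5727;5728
metastatic_solid_tumor,6,any_malignancy,196;197;198;1990;1991
aids,6,,042;043;044
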