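participant_id,study_id,arm,age_years,cp_0,cp_3,cp_6,cp_9,cp_12
ex_001,Example,control,10,0.66,0.60,0.55,0.47,0.40
ex_002,Example,active,16.4,0.73,0.74,0.70,0.69,0.68
ex_003,Example,control,24.5,0.84,0.78,,0.66,0.61
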