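patient_id,age,sex,ethnicity
EX01,34,Female,Caucasian
EX02,41,Male,Asian
EX03,29,Female,Other
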