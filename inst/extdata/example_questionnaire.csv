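patient_id,timepoint,mood_category,mood_sublevel,side_effects
EX01,baseline,unable,high,fatigue;dizziness;insomnia
EX02,baseline,unable,low,fatigue;weight gain;nausea;tremor
EX03,baseline,force_myself,high,fatigue
EX01,followup,feel_good,,
EX02,followup,force_myself,low,fatigue
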