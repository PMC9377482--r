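item_id,label,completed_when
measure_lactate,Measure serum lactate; remeasure if initial lactate > 2 mmol/L,lactate_present
blood_cultures,Obtain blood cultures before administering antibiotics,blood_culture_ordered
broad_spectrum_antibiotics,Administer broad-spectrum antibiotics,antibiotics_ordered
crystalloid_bolus,Begin 30 mL/kg crystalloid for hypotension or lactate >= 4 mmol/L,never
vasopressors_for_map,Apply vasopressors if MAP < 65 mmHg after fluid resuscitation,vasopressor_ordered
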