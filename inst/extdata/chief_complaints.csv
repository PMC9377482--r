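code,label
abdominal_pain,Abdominal pain
chest_pain,Chest pain
dyspnea,Shortness of breath
fever,Fever
headache,Headache
dizziness,Dizziness
syncope,Syncope
altered_mental_status,Altered mental status
seizure,Seizure
injury,Injury
back_pain,Back pain
vomiting,Vomiting
diarrhea,Diarrhea
bleeding,Bleeding
palpitations,Palpitations
weakness,Generalized weakness
rash,Rash
sore_throat,Sore throat
urinary_symptoms,Urinary symptoms
extremity_pain,Extremity pain
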