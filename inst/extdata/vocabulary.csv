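source_system,source_code,feature_name,omop_concept_id,canonical_unit
LOINC,9269-2,gcs,3032652,1
LOINC,8480-6,sbp,3004249,mm[Hg]
LOINC,8462-4,dbp,3012888,mm[Hg]
LOINC,9279-1,resp_rate,3024171,/min
LOINC,8310-5,body_temperature,3020891,Cel
LOINC,2703-7,pao2,3027315,mm[Hg]
LOINC,3150-0,fio2,3020716,1
LOINC,777-3,platelets,3024929,10*3/uL
LOINC,2160-0,creatinine,3016723,mg/dL
LOINC,1975-2,total_bilirubin,3024128,mg/dL
LOINC,2524-7,lactate,3047181,mmol/L
LOINC,8867-4,heart_rate,3027018,/min
LOINC,59408-5,spo2,40762499,%
LOINC,67775-7,mental_status_avpu,3328462,coded
LOINC,8661-1,chief_complaint,3037113,coded
LOINC,74287-4,onset_to_visit,40771922,h
LOINC,67494-5,trauma_flag,45876743,1
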