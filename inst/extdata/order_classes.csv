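feature_name,resource_kind,system,code_prefix
antibiotics_ordered,MedicationRequest,ATC,J01
vasopressor_ordered,MedicationRequest,ATC,C01CA
blood_culture_ordered,ServiceRequest,SNOMED,30088009
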