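from_unit,to_unit,formula_id
degF,Cel,fahrenheit_to_celsius
[degF],Cel,fahrenheit_to_celsius
K,Cel,kelvin_to_celsius
%,1,percent_to_fraction
mmHg,mm[Hg],identity
torr,mm[Hg],identity
10*9/L,10*3/uL,identity
g/L,mg/dL,per_litre_to_per_decilitre_mg
umol/L_creatinine,mg/dL,umol_per_l_creatinine_to_mg_per_dl
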