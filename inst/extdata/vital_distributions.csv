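feature,status,mean,sd,lo,hi
body_temperature,normal,36.8,0.4,35.5,37.8
body_temperature,deranged,38.7,0.8,36.5,41.5
sbp,normal,122,14,90,180
sbp,deranged,92,18,55,150
dbp,normal,76,10,50,110
dbp,deranged,55,12,30,95
resp_rate,normal,16,2.5,10,24
resp_rate,deranged,26,5,12,45
heart_rate,normal,82,12,50,120
heart_rate,deranged,115,18,60,180
spo2,normal,97.5,1.2,92,100
spo2,deranged,91,4,70,100
pao2,normal,95,10,70,120
pao2,deranged,70,15,40,110
fio2,normal,0.21,0.0,0.21,0.21
fio2,deranged,0.45,0.15,0.21,1.0
platelets,normal,250,60,120,450
platelets,deranged,110,60,5,300
creatinine,normal,0.9,0.2,0.4,1.4
creatinine,deranged,2.4,1.4,0.5,8.0
total_bilirubin,normal,0.7,0.3,0.1,1.5
total_bilirubin,deranged,3.5,3.0,0.3,20.0
lactate,normal,1.2,0.4,0.4,2.4
lactate,deranged,3.8,1.8,0.8,12.0
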