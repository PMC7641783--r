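variable,interval,points
age,<30,0
age,30-48,5
age,48-78,14
age,78-85,22
age,>=85,24
heart_rate,<62,1
heart_rate,62-72,0
heart_rate,72-98,1
heart_rate,98-112,8
heart_rate,>=112,13
resp_rate,<12,3
resp_rate,12-16,0
resp_rate,16-22,4
resp_rate,>=22,12
sbp,<90,15
sbp,90-100,8
sbp,100-130,0
sbp,130-150,1
sbp,>=150,3
temperature,<36,12
temperature,36-36.5,3
temperature,36.5-37.5,0
temperature,37.5-38,5
temperature,>=38,9
spo2,<85,25
spo2,85-90,13
spo2,90-95,4
spo2,>=95,0
platelet,<80,17
platelet,80-150,3
platelet,150-300,0
platelet,300-450,3
platelet,>=450,5
bun,<7.5,0
bun,7.5-12,2
bun,12-35,9
bun,35-70,19
bun,>=70,23
lactate,<1,0
lactate,1-2.5,2
lactate,2.5-4,8
lactate,>=4,21
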