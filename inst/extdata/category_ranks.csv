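phenotype,symptoms,descriptions,medicine,body,numbers,verbs,others
Adv. Cancer,2,1,5,7,6,4,3
Adv. Heart Disease,1,4,5,7,2,6,3
Adv. Lung Disease,1,5,7,3,6,4,2
Chronic Neuro,1,2,3,6,7,5,4
Chronic Pain,1,4,2,5,7,6,3
Alcohol Abuse,1,6,2,5,4,7,3
Substance Abuse,1,4,2,5,6,7,3
Obesity,7,1,6,4,5,2,3
Psychiatric Disorders,1,3,4,2,7,6,5
Depression,1,2,3,7,6,5,4
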