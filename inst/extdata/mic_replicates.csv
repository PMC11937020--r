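organism,condition,replicate,mic_ug_ml
ecoli,control,1,128
ecoli,control,2,256
ecoli,control,3,128
ecoli,control,4,128
ecoli,drought,1,512
ecoli,drought,2,512
ecoli,drought,3,512
ecoli,drought,4,512
ecoli,salt_high,1,512
ecoli,salt_high,2,512
ecoli,salt_high,3,512
ecoli,salt_high,4,512
saureus,control,1,256
saureus,control,2,256
saureus,control,3,128
saureus,control,4,128
saureus,drought,1,1024
saureus,drought,2,1024
saureus,drought,3,1024
saureus,drought,4,1024
saureus,salt_high,1,512
saureus,salt_high,2,512
saureus,salt_high,3,512
saureus,salt_high,4,512
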