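gene,genotype,replicate,ct
actin,inermis,1,20.052
actin,inermis,2,19.774
actin,inermis,3,19.884
actin,stramonium,1,20.006
actin,stramonium,2,20.03
actin,stramonium,3,19.667
actin,tatula,1,19.756
actin,tatula,2,19.87
actin,tatula,3,20.232
PMT,inermis,1,25.808
PMT,inermis,2,26.253
PMT,inermis,3,26.245
PMT,stramonium,1,25.185
PMT,stramonium,2,25.272
PMT,stramonium,3,25.227
PMT,tatula,1,24.88
PMT,tatula,2,24.801
PMT,tatula,3,24.766
TR1,inermis,1,25.941
TR1,inermis,2,25.851
TR1,inermis,3,26.04
TR1,stramonium,1,24.969
TR1,stramonium,2,24.98
TR1,stramonium,3,24.889
TR1,tatula,1,24.96
TR1,tatula,2,24.546
TR1,tatula,3,24.589
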