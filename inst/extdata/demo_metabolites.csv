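genotype,cpd01,cpd02,cpd03,cpd04,cpd05,cpd06,cpd07,cpd08,cpd09,cpd10
stramonium,0.7004,1.4299,0.9946,0.9283,0.8968,1.4671,0.8688,1.0215,0.9233,0
tatula,1.694,0,0.9231,0,0.8122,0,0,0,1.1333,1.1172
inermis,0.7385,1.1217,0.782,1.1146,0,0.7846,0.5456,0.8012,1.1217,1.6808
metel,1.6915,0.8485,0.7729,0,0.9418,0.7181,1.0748,1.1211,1.9526,1.433
ferox,0.7741,0,1.5869,0,1.5992,1.0778,0.555,0.7845,0.861,1.0959
innoxia,1.0348,0,0,0,0,0,1.273,0.8028,0.6154,1.2862
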