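concentration,absorbance
0,0.0614
0.125,1.112
0.25,2.1425
0.5,4.0536
0.75,6.1048
1,8.0759
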