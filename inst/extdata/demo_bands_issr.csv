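primer,band_bp,stramonium,tatula,inermis,metel,ferox,innoxia
ISSR-01,2186,1,1,1,1,1,1
ISSR-01,1040,1,1,1,1,1,1
ISSR-01,2359,1,1,1,1,1,1
ISSR-01,1244,1,1,1,0,1,1
ISSR-01,2068,1,1,1,1,1,0
ISSR-01,2350,0,1,1,0,1,1
ISSR-01,645,1,1,1,0,0,0
ISSR-01,184,1,1,1,0,0,1
ISSR-02,494,1,1,1,1,1,1
ISSR-02,2072,0,0,0,0,1,1
ISSR-02,2811,1,1,1,1,1,1
ISSR-02,1696,1,1,1,1,1,1
ISSR-02,1845,1,1,1,0,0,0
ISSR-02,671,1,1,0,0,0,0
ISSR-02,1652,1,1,1,0,0,0
ISSR-02,621,0,0,0,0,1,1
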