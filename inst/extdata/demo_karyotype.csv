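genotype,cell,chromosome,short_arm_um,long_arm_um
stramonium,1,1,1.355,2.309
stramonium,1,2,1.877,2.677
stramonium,1,3,1.225,2.273
stramonium,1,4,1.401,2.627
stramonium,1,5,2.006,2.679
stramonium,1,6,1.644,2.115
stramonium,1,7,1.478,2.333
stramonium,1,8,1.349,2.397
stramonium,1,9,1.272,2.613
stramonium,1,10,1.446,2.609
stramonium,1,11,1.565,2.926
stramonium,1,12,1.344,2.335
stramonium,1,13,1.587,1.98
stramonium,1,14,1.968,1.968
stramonium,1,15,1.734,1.837
stramonium,1,16,1.601,2.344
stramonium,1,17,1.303,2.459
stramonium,1,18,1.36,1.767
stramonium,1,19,1.651,2.445
stramonium,1,20,1.31,2.586
stramonium,1,21,1.828,2.533
stramonium,1,22,1.658,2.719
stramonium,1,23,2.013,2.574
stramonium,1,24,1.796,2.487
stramonium,2,1,1.434,2.276
stramonium,2,2,1.584,2.389
stramonium,2,3,1.761,2.824
stramonium,2,4,1.656,2.419
stramonium,2,5,1.607,2.802
stramonium,2,6,1.487,2.276
stramonium,2,7,1.553,2.402
stramonium,2,8,1.539,2.091
stramonium,2,9,1.639,2.662
stramonium,2,10,1.916,2.039
stramonium,2,11,1.448,2.526
stramonium,2,12,1.641,2.452
stramonium,2,13,1.328,2.217
stramonium,2,14,1.87,2.472
stramonium,2,15,1.217,2.552
stramonium,2,16,1.763,2.436
stramonium,2,17,1.49,2.206
stramonium,2,18,1.63,2.233
stramonium,2,19,1.157,2.003
stramonium,2,20,1.736,2.143
stramonium,2,21,1.323,2.168
stramonium,2,22,1.427,2.461
stramonium,2,23,1.426,2.492
stramonium,2,24,1.506,2.404
ferox,1,1,1.33,2.778
ferox,1,2,1.316,2.432
ferox,1,3,1.842,2.505
ferox,1,4,2.011,2.679
ferox,1,5,1.529,2.481
ferox,1,6,1.881,2.267
ferox,1,7,1.555,1.921
ferox,1,8,1.543,2.753
ferox,1,9,1.633,2.385
ferox,1,10,1.347,2.233
ferox,1,11,1.615,3.076
ferox,1,12,1.439,2.089
ferox,1,13,2.031,2.23
ferox,1,14,1.691,2.162
ferox,1,15,1.572,2.188
ferox,1,16,1.68,2.342
ferox,1,17,1.906,2.777
ferox,1,18,1.391,2.172
ferox,1,19,1.679,2.205
ferox,1,20,2.008,2.875
ferox,1,21,1.423,2.784
ferox,1,22,1.373,2.065
ferox,1,23,1.887,2.919
ferox,1,24,1.418,2.107
ferox,1,25,1.559,2.518
ferox,1,26,1.503,2.03
ferox,1,27,1.415,2.57
ferox,2,1,1.424,2.118
ferox,2,2,1.45,2.983
ferox,2,3,1.357,2.031
ferox,2,4,1.595,1.775
ferox,2,5,1.835,2.119
ferox,2,6,1.409,2.635
ferox,2,7,1.677,2.409
ferox,2,8,1.746,2.476
ferox,2,9,1.543,2.034
ferox,2,10,1.668,1.688
ferox,2,11,1.483,2.382
ferox,2,12,1.46,2.622
ferox,2,13,1.433,2.478
ferox,2,14,1.441,2.195
ferox,2,15,1.769,1.908
ferox,2,16,1.536,2.685
ferox,2,17,1.655,2.189
ferox,2,18,1.625,2.196
ferox,2,19,1.787,2.204
ferox,2,20,1.66,2.1
ferox,2,21,1.536,2.34
ferox,2,22,1.481,2.246
ferox,2,23,1.74,2.179
ferox,2,24,1.792,2.655
ferox,2,25,1.772,2.559
ferox,2,26,1.826,2.674
ferox,2,27,1.915,3.128
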