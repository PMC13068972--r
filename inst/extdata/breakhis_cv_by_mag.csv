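magnification,fold1,fold2,fold3,fold4,fold5
40,89.5,90.1,89.8,90.3,89.7
100,91.0,91.8,91.2,92.1,91.5
200,91.8,92.3,91.9,92.6,92.1
400,92.4,93.1,92.7,93.4,92.9
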