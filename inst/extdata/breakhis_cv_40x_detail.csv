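fold,train,val,test,precision,f1
1,95.1,92.3,91.9,91.6,91.5
2,95.3,92.6,92.2,91.9,91.8
3,95.0,92.4,92.0,91.7,91.6
4,95.2,92.5,92.1,91.8,91.7
5,95.4,92.7,92.3,92.0,91.9
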