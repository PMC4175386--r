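dataset,factor,level1,level2,level3
dermatology,A,10,50,100
dermatology,B,2.4,5,10
zoo,A,5,10,50
zoo,B,0.08,4,11
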