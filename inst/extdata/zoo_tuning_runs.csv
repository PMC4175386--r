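run,level_A,level_B,y1,y2,y3,y4,y5,average,sn
1,1,1,0.9513,0.9673,0.9435,0.9567,0.9546,0.9547,-0.4037
2,1,2,0.9600,0.9616,0.9588,0.9611,0.9608,0.9605,-0.3504
3,1,3,0.7809,0.7833,0.7820,0.7679,0.7811,0.7790,-2.1694
4,2,1,0.7118,0.6766,0.7368,0.7256,0.7109,0.7123,-2.9571
5,2,2,0.9600,0.9612,0.9604,0.9519,0.9440,0.9555,-0.3960
6,2,3,0.8900,0.8947,0.9214,0.9050,0.9190,0.9060,-0.8598
7,3,1,0.7118,0.7398,0.7421,0.7495,0.7203,0.7327,-2.7064
8,3,2,0.9610,0.9735,0.9709,0.9752,0.9661,0.9693,-0.2709
9,3,3,0.9600,0.9723,0.9707,0.9509,0.9763,0.9660,-0.3013
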