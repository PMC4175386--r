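run,level_A,level_B,y1,y2,y3,y4,y5,average,sn
1,1,1,0.9631,0.9701,0.9697,0.9627,0.9614,0.9654,-0.3060
2,1,2,0.9686,0.9749,0.9653,0.9621,0.9732,0.9688,-0.2755
3,1,3,0.9795,0.9847,0.9848,0.9838,0.9735,0.9813,-0.1647
4,2,1,0.9630,0.9615,0.9581,0.9599,0.9668,0.9619,-0.3379
5,2,2,0.9687,0.9721,0.9704,0.9707,0.9626,0.9689,-0.2746
6,2,3,0.9685,0.9748,0.9744,0.9712,0.9707,0.9719,-0.2475
7,3,1,0.9671,0.9689,0.9648,0.9668,0.9645,0.9664,-0.2967
8,3,2,0.9741,0.9704,0.9797,0.9799,0.9767,0.9762,-0.2098
9,3,3,0.9625,0.9633,0.9642,0.9678,0.9619,0.9639,-0.3191
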