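participant,Pacc,F1,Psen,Pspe
1,0.5667,0.7111,0.5926,0.3333
2,0.5167,0.6667,0.5686,0.2222
3,0.5333,0.6818,0.5769,0.2500
4,0.5667,0.7174,0.5893,0.2500
5,0.5167,0.6588,0.5714,0.2727
6,0.4500,0.5479,0.5405,0.3043
7,0.5167,0.6420,0.5778,0.3333
8,0.6167,0.6761,0.6857,0.5200
9,0.6333,0.7609,0.6250,0.7500
10,0.5833,0.7191,0.6038,0.4286
11,0.5500,0.7097,0.5789,0.0000
12,0.5667,0.7111,0.5926,0.3333
13,0.5833,0.7191,0.6038,0.4286
14,0.6167,0.7356,0.6275,0.5556
15,0.5000,0.6512,0.5600,0.2000
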