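participant,Pacc,F1,Psen,Pspe
1,0.6167,0.5978,0.6944,0.5000
2,0.6167,0.5632,0.8056,0.3333
3,0.5167,0.4745,0.6667,0.2917
4,0.5333,0.4976,0.6667,0.3333
5,0.5667,0.5335,0.6944,0.3750
6,0.5333,0.4750,0.7222,0.2500
7,0.5333,0.4750,0.7222,0.2500
8,0.5667,0.5335,0.6944,0.3750
9,0.4833,0.4489,0.6111,0.2917
10,0.5667,0.5238,0.7222,0.3333
11,0.6000,0.5604,0.7500,0.3750
12,0.5333,0.4444,0.7778,0.1667
13,0.6167,0.5632,0.8056,0.3333
14,0.5833,0.5369,0.7500,0.3333
15,0.6333,0.5875,0.8056,0.3750
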