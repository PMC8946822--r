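participant,Z,M,none
1,0.4333,0.5667,0
2,0.4083,0.5917,0
3,0.3583,0.6417,0
4,0.3333,0.6667,0
5,0.2917,0.6667,0.0417
6,0.4250,0.5750,0
7,0.1417,0.8167,0.0417
8,0.4917,0.4500,0.0583
9,0.3750,0.6250,0
10,0.4083,0.5917,0
11,0.5000,0.5000,0
12,0.3750,0.6083,0.0167
13,0.3083,0.6417,0.0500
14,0.3000,0.7000,0
15,0.4667,0.5250,0.0083
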