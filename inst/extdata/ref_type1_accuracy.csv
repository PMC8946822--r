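participant,n_correct,rate
1,78,0.9750
2,77,0.9625
3,77,0.9625
4,78,0.9750
5,75,0.9375
6,79,0.9875
7,75,0.9375
8,45,0.5625
9,80,1.0000
10,79,0.9875
11,74,0.9250
12,77,0.9625
13,74,0.9250
14,77,0.9625
15,78,0.9750
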