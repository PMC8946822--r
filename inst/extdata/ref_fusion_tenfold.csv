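participant,Pacc,F1,Psen,Pspe
1,0.5500,0.4980,0.7149,0.3254
2,0.6200,0.5520,0.7984,0.3473
3,0.5550,0.4826,0.7469,0.2637
4,0.6000,0.5627,0.7285,0.4485
5,0.5050,0.4340,0.6663,0.2387
6,0.6150,0.5739,0.7109,0.4549
7,0.5350,0.4907,0.6486,0.3477
8,0.5750,0.5221,0.7148,0.3435
9,0.4650,0.4138,0.6105,0.2420
10,0.5150,0.4675,0.6625,0.3103
11,0.5650,0.5206,0.6899,0.3654
12,0.4950,0.4512,0.6457,0.2854
13,0.6200,0.5536,0.7933,0.3608
14,0.5750,0.5217,0.7404,0.3936
15,0.5700,0.5278,0.7172,0.3776
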