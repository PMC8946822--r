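participant,M0,V0_1e5,M1,V1_1e5,p_printed
1,922.8000,5.5430,394.8250,0.6054,<0.0001
2,906.8083,3.9771,750.3625,3.0268,0.0723
3,1671.3250,12.6708,1255.1625,9.6150,0.0077
4,600.6000,1.5579,498.1500,0.8538,0.0484
5,817.0417,5.1775,691.6750,5.3187,0.2313
6,663.7000,2.4416,483.1625,1.0309,0.0043
7,954.4167,6.6568,634.8375,3.4308,0.0028
8,952.7917,3.4874,1042.3250,4.1254,0.3118
9,1352.3917,3.2787,1024.6000,2.5207,<0.0001
10,585.9167,0.6708,508.0875,0.2722,0.0181
11,489.8833,1.1614,501.4000,0.8066,0.8030
12,776.2667,2.6158,665.5500,2.9460,0.1449
13,795.8667,2.9384,716.9125,3.7115,0.3382
14,556.5417,2.1436,555.7375,4.3380,0.9919
15,648.1417,1.5386,611.2625,0.8704,0.4746
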