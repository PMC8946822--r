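channel,theta_p,theta_t,alpha_p,alpha_t,bg_p,bg_t
AF3,0.5606,-0.5820,0.5729,-0.5638,0.3213,-0.9921
AF4,0.2631,-1.1194,0.6316,-0.4795,0.8329,-0.2109
F3,0.0036,-2.9111,0.4954,-0.6818,0.1418,-1.4696
F4,0.8912,0.1368,0.0707,1.8083,0.0829,-1.7347
P7,0.6886,-0.4008,0.0001,-3.9306,0.4052,-0.8325
P8,0.5807,-0.5524,0.0003,-3.6612,0.2001,-1.2815
O1,0.2673,-1.1096,0.2236,-1.2172,0.1417,-1.4699
O2,0.1478,-1.4479,0.2272,-1.2078,0.6872,-0.4027
F7,0.4698,-0.7229,0.0717,-1.8019,0.4439,-0.7657
F8,0.0001,-3.9354,0.9440,-0.0702,0.0238,-2.2619
FC5,0.0003,-3.6126,0.3226,-0.9894,0.1056,-1.6187
FC6,0.0001,-4.2182,0.2153,-1.2395,0.1850,-1.3260
T7,0.5987,-0.5263,0.2464,1.1595,0.0885,-1.7041
T8,0.5893,-0.5399,0.2876,-1.0635,0.0443,-2.0122
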