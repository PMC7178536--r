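batch,GV_esm,GC_esm,GC_qams,GC_re,C_esm,C_qams,C_re,V_esm,V_qams,V_re,GH_esm,GH_qams,GH_re,H_esm,H_qams,H_re
1,2.896,4.295,4.289,-0.14,1.048,1.047,-0.10,0.09829,0.09793,-0.37,1.069,1.070,0.09,0.06459,0.06460,0.02
2,0.8574,2.646,2.642,-0.15,0.3916,0.3914,-0.05,0.04527,0.04511,-0.35,0.2362,0.2364,0.08,0.1061,0.1061,0.00
3,1.889,3.783,3.778,-0.13,0.7479,0.7475,-0.05,0.06943,0.06918,-0.36,0.9545,0.9553,0.08,0.1507,0.1507,0.00
4,2.480,2.885,2.881,-0.14,0.2100,0.2098,-0.10,0.05922,0.05901,-0.35,0.2845,0.2847,0.07,0.02008,0.02009,0.05
5,2.848,3.510,3.505,-0.14,0.9254,0.9248,-0.06,0.08080,0.08051,-0.36,0.7045,0.7051,0.09,0.06158,0.06159,0.02
6,1.832,2.019,2.016,-0.15,0.6268,0.6264,-0.06,0.05237,0.05219,-0.34,0.2341,0.2343,0.09,0.02235,0.02236,0.04
7,1.961,2.241,2.239,-0.09,0.5400,0.5396,-0.07,0.05959,0.05937,-0.37,0.2508,0.2510,0.08,0.07276,0.07278,0.03
8,2.062,2.249,2.246,-0.13,0.2459,0.2458,-0.04,0.06527,0.06503,-0.37,0.2155,0.2157,0.09,0.02565,0.02565,0.00
9,1.390,4.122,4.123,0.02,0.3810,0.3809,-0.03,0.03938,0.03918,-0.51,0.4580,0.4593,0.28,0.08772,0.08785,0.15
10,3.961,2.466,2.466,0.00,1.469,1.469,0.00,0.2263,0.2251,-0.53,1.264,1.267,0.24,0.3047,0.3051,0.13
11,2.004,3.054,3.054,0.00,1.491,1.491,0.00,0.1301,0.1294,-0.54,0.7997,0.8018,0.26,0.1760,0.1763,0.17
12,2.519,2.363,2.363,0.00,1.029,1.030,0.10,0.08996,0.08953,-0.48,0.6982,0.6997,0.21,0.06253,0.06263,0.16
13,2.848,4.417,4.416,-0.02,1.754,1.756,0.11,0.1763,0.1754,-0.51,0.9507,0.9528,0.22,0.1461,0.1463,0.14
14,2.233,4.983,4.983,0.00,0.799,0.7997,0.09,0.07737,0.07700,-0.48,0.8065,0.8082,0.21,0.07475,0.07487,0.16
15,4.038,3.972,3.973,0.03,1.239,1.238,-0.08,0.1380,0.1372,-0.58,0.6367,0.6384,0.27,0.05454,0.05462,0.15
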