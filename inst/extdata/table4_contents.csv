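batch,GC,C,GV,V,GH,H,total
1,1.317,0.4275,1.261,0.02920,0.2946,0.03354,3.363
2,2.418,0.4976,2.382,0.04779,0.3659,0.03554,5.747
3,2.651,0.5458,2.698,0.06159,0.3781,0.02972,6.364
4,1.337,0.6792,1.654,0.04434,0.2859,0.06364,4.064
5,2.689,0.2197,2.876,0.03020,0.3112,0.01964,6.146
6,4.573,1.107,1.955,0.03020,0.5887,0.08134,8.335
7,1.729,0.4001,1.835,0.03092,0.1675,0.02509,4.188
8,2.564,0.3944,3.718,0.04341,0.2723,0.02125,7.013
9,2.430,0.1014,2.255,0.03667,0.2496,0.01529,5.088
10,2.258,0.6732,2.216,0.00000,0.3463,0.05838,5.552
11,1.304,0.344,1.449,0.03023,0.3543,0.06303,3.545
12,2.452,0.1243,2.755,0.03687,0.1534,0.05423,5.576
13,1.346,0.9504,1.465,0.06466,0.3278,0.11580,4.270
14,1.777,0.5765,1.127,0.02988,0.2396,0.08358,3.834
15,1.786,0.6144,1.364,0.03312,0.1714,0.05189,4.021
16,2.896,0.422,2.682,0.06387,0.5827,0.09963,6.746
17,4.69,1.02,2.551,0.10200,1.1490,0.15070,9.663
18,1.043,0.2811,1.573,0.02553,0.1242,0.00000,3.047
19,1.717,0.6368,1.962,0.08296,0.2502,0.15210,4.801
20,2.28,0.983,2.533,0.09785,0.3417,0.07771,6.313
21,2.729,0.3448,2.464,0.04038,0.2646,0.02275,5.866
22,4.2,1.147,3.442,0.14280,0.6112,0.06122,9.604
23,2.139,0.1695,1.929,0.00000,0.3146,0.01560,4.568
24,2.744,0.8955,2.324,0.08142,0.7392,0.1081,6.892
25,4.45,1.843,2.509,0.09471,0.6873,0.07324,9.657
26,2.817,1.401,2.608,0.09266,0.9524,0.07638,7.947
27,2.368,0.5529,2.202,0.05162,0.3305,0.07492,5.580
28,1.487,0.1982,1.880,0.03231,0.1906,0.01684,3.805
29,3.599,0.6820,2.030,0.04863,0.5045,0.06149,6.926
30,2.116,1.4090,3.498,0.11720,0.3130,0.04773,7.501
31,4.237,1.2030,1.818,0.03805,0.7812,0.06076,8.138
32,2.077,0.9935,2.653,0.08411,0.3187,0.07907,6.205
33,2.221,1.1080,2.931,0.10130,0.2647,0.06694,6.693
34,1.863,0.3630,0.941,0.03012,0.3419,0.07997,3.619
35,1.818,0.3075,1.096,0.00000,0.3717,0.12460,3.718
36,2.134,0.3686,1.076,0.00000,0.1803,0.06089,3.820
37,2.173,1.3010,1.232,0.04985,0.5113,0.12210,5.389
38,3.773,0.3078,3.220,0.06403,0.3651,0.02726,7.757
39,2.234,0.4056,1.289,0.00000,0.1985,0.03652,4.164
40,2.168,0.4823,1.776,0.00000,0.2772,0.05842,4.762
41,1.490,0.4874,1.240,0.00000,0.3820,0.12980,3.729
42,1.708,0.3880,1.587,0.00000,0.3404,0.13020,4.154
43,1.834,0.2949,2.261,0.03667,0.1705,0.02114,4.618
44,2.199,0.5615,2.569,0.06130,0.2619,0.13020,5.783
45,3.667,1.3310,3.572,0.12560,0.8210,0.08447,9.601
46,1.985,0.1671,1.610,0.04060,0.1129,0.03844,3.954
47,1.765,0.2047,1.508,0.03583,0.1699,0.00000,3.683
48,2.363,1.0300,2.519,0.08953,0.6997,0.06263,6.764
49,3.670,1.3180,1.900,0.11270,0.8467,0.18620,8.034
50,2.447,0.5516,1.778,0.07714,0.4362,0.07921,5.369
51,2.466,1.4690,3.961,0.22510,1.2670,0.30510,9.693
52,4.416,1.7560,2.848,0.17540,0.9528,0.14630,10.300
53,5.136,1.2960,3.769,0.17010,0.7804,0.07168,11.220
54,1.901,0.5797,0.953,0.03516,0.2994,0.10780,3.876
55,1.825,0.3481,0.867,0.03686,0.3172,0.09194,3.486
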