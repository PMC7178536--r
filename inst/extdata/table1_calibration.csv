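analyte,slope,intercept,r,range_min,range_max,lod,loq
GC,1815300,8028,0.9999,2.10,209.60,0.29,0.96
C,2928940,7329,0.9999,1.22,122.00,0.28,0.92
GV,1894482,14466,0.9999,3.34,334.00,0.28,0.94
V,3222987,4879,0.9999,0.81,80.80,0.18,0.61
GH,2660022,6702,0.9999,1.64,163.60,0.22,0.73
H,4418335,1757,0.9999,0.37,36.90,0.09,0.31
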