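compound,ALOGPs,AClogP,ALOGP,MLOGP,XLOGP2,XLOGP3,LogP,ClogP
1,4.90,4.66,4.58,2.78,4.72,4.48,4.54,5.23
2,4.61,5.37,4.79,3.01,5.02,4.62,4.92,5.09
3,5.06,5.97,5.40,3.39,5.64,5.26,5.35,5.86
4,4.87,5.26,5.98,3.39,5.29,4.73,4.77,5.51
5,4.93,4.66,4.58,3.17,4.72,4.48,4.54,5.13
6,4.64,5.37,4.79,3.40,5.02,4.62,4.92,5.03
7,5.06,5.97,5.40,3.78,5.64,5.26,5.35,5.80
8,4.91,5.26,5.98,3.78,5.29,4.73,4.77,5.48
9,4.92,4.66,5.58,3.17,4.72,4.48,4.41,5.13
10,4.64,5.37,4.79,3.40,5.02,4.64,4.92,5.03
11,4.93,4.66,4.58,3.17,4.72,4.48,4.87,5.13
12,4.59,5.37,4.79,3.40,5.02,4.62,4.92,5.03
13,5.04,5.97,5.40,3.78,5.64,5.26,5.35,5.80
14,5.87,5.53,5.30,4.24,5.88,5.46,5.63,6.12
15,5.54,6.24,5.51,4.47,6.19,5.60,5.80,6.12
16,6.10,6.84,6.13,4.83,6.80,6.24,6.28,6.90
17,5.63,6.13,6.70,4.83,6.45,5.72,5.98,6.54
18,5.85,5.53,5.30,4.24,5.88,5.46,5.63,6.11
19,5.54,6.24,5.51,4.47,6.19,5.60,5.80,6.12
20,6.05,6.84,6.13,4.83,6.80,6.24,6.28,6.90
21,5.60,6.13,6.70,4.83,6.45,5.72,5.98,6.54
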