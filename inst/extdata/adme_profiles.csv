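compound,caco2_pe,ppb_pct,cns,hia_pct,pgp_score,cyp1a2,cyp2c9,cyp2c19,cyp2d6,cyp3a4
1,226,99,-3.30,100,0.30,0.61,0.34,0.49,0.48,0.53
2,231,99,-3.23,100,0.38,0.57,0.26,0.49,0.46,0.50
3,207,100,-3.44,100,0.35,0.62,0.33,0.52,0.48,0.53
4,235,100,-3.96,100,0.35,0.68,0.40,0.51,0.42,0.54
5,226,99,-3.30,100,0.30,0.58,0.34,0.50,0.48,0.58
6,231,99,-3.23,100,0.38,0.61,0.26,0.49,0.46,0.54
7,207,100,-3.44,100,0.35,0.55,0.33,0.51,0.48,0.53
8,235,100,-3.96,100,0.35,0.67,0.40,0.50,0.37,0.54
9,230,99,-3.30,100,0.30,0.58,0.34,0.50,0.48,0.58
10,231,99,-3.23,100,0.38,0.61,0.26,0.49,0.46,0.54
11,211,99,-3.30,100,0.30,0.58,0.34,0.50,0.48,0.58
12,231,99,-3.23,100,0.38,0.61,0.26,0.49,0.46,0.54
13,207,100,-3.44,100,0.35,0.55,0.33,0.51,0.48,0.53
14,131,100,-3.51,100,0.28,0.66,0.33,0.51,0.49,0.53
15,163,100,-3.40,100,0.38,0.68,0.26,0.53,0.47,0.50
16,94,100,-3.72,100,0.38,0.63,0.32,0.57,0.50,0.51
17,137,100,-4.30,100,0.34,0.71,0.39,0.53,0.43,0.56
18,131,100,-3.51,100,0.28,0.66,0.33,0.51,0.49,0.53
19,163,100,-3.40,100,0.38,0.68,0.26,0.53,0.47,0.50
20,94,100,-3.72,100,0.38,0.63,0.32,0.57,0.50,0.51
21,137,100,-4.30,100,0.34,0.71,0.39,0.53,0.43,0.56
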