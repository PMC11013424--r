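compound,rm0,r,b,logp_tlc
1,3.15,0.9953,-0.0383,4.26
2,4.14,0.9954,-0.0503,5.57
3,4.30,0.9944,-0.058,5.77
4,3.35,0.9953,-0.0383,4.56
5,3.72,0.9927,-0.0459,5.03
6,4.24,0.9982,-0.0582,5.69
7,4.46,0.9988,-0.0534,5.97
8,3.96,0.9987,-0.0539,5.34
9,3.69,0.9969,-0.0498,4.99
10,4.37,0.9977,-0.0540,5.86
11,3.48,0.9960,-0.0462,4.72
12,4.21,0.9989,-0.0576,5.65
13,3.58,0.9928,-0.0478,4.85
14,4.24,0.9967,-0.0573,5.69
15,4.49,0.9965,-0.0527,6.01
16,4.60,0.9979,-0.0571,6.15
17,4.29,0.9985,-0.0529,5.76
18,3.81,0.9934,-0.0484,5.14
19,4.18,0.9931,-0.0538,5.58
20,4.34,0.9973,-0.0548,5.82
21,4.09,0.9977,-0.0507,5.50
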