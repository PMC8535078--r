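environment,width,length,roundness,oil,protein,beta_glucan
1,3.10,10.83,0.287,7.82,8.42,3.72
2,3.13,12.79,0.245,7.03,10.40,4.61
3,3.06,10.74,0.286,7.79,7.77,4.70
4,3.30,11.04,0.300,7.33,10.18,3.82
5,3.34,10.69,0.312,7.21,9.54,4.44
6,3.25,11.79,0.276,7.37,9.59,4.35
7,3.19,10.42,0.306,7.21,9.65,3.61
8,3.08,12.58,0.244,6.48,12.11,4.88
9,3.11,11.09,0.281,7.24,8.36,4.60
10,3.16,12.31,0.258,7.66,11.85,4.11
11,3.27,11.10,0.295,6.59,11.10,3.98
12,3.19,10.67,0.300,7.27,10.83,4.19
13,3.18,12.24,0.262,7.00,10.88,3.97
14,3.13,12.18,0.258,7.34,9.70,4.29
15,3.31,10.86,0.306,7.83,9.06,3.35
16,3.08,11.92,0.259,6.99,9.97,4.63
17,3.20,10.79,0.297,7.69,8.42,4.27
18,3.14,10.26,0.307,7.74,8.95,3.16
19,3.08,12.55,0.246,7.59,8.79,4.21
20,3.21,10.98,0.293,7.19,7.88,4.43
21,3.11,10.52,0.297,7.23,10.88,3.74
22,2.94,10.67,0.276,7.70,12.33,4.61
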