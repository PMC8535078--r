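environment,yield,grain_number,groat_content,hullability,hectoliter_weight,tgw
1,6.03,16.03,68.65,90.07,43.14,37.65
2,8.31,19.90,73.45,77.46,50.17,41.89
3,9.31,24.83,68.88,83.44,50.26,37.92
4,8.08,18.20,75.49,93.60,46.01,44.96
5,7.92,16.56,75.48,91.36,53.66,48.18
6,10.02,22.06,75.23,88.32,55.35,45.27
7,6.77,16.78,73.42,98.50,44.47,40.41
8,4.96,12.38,75.73,93.03,50.89,41.40
9,7.18,17.41,74.13,86.82,49.24,41.74
10,10.19,24.16,74.68,71.34,52.94,42.00
11,4.84,10.88,75.88,99.58,51.12,44.55
12,7.98,18.97,73.97,91.34,59.57,42.55
13,7.26,17.85,73.55,93.06,49.65,40.66
14,9.74,23.24,72.91,76.37,51.88,42.04
15,7.61,17.35,73.08,95.55,,44.60
16,8.79,22.02,73.22,84.52,52.13,40.23
17,9.69,22.45,72.99,80.28,53.17,43.25
18,6.83,17.86,69.72,97.52,,38.40
19,10.49,26.62,72.55,75.76,51.76,39.66
20,9.94,22.94,72.73,83.17,50.99,43.62
21,8.20,20.62,74.36,97.23,42.64,39.47
22,9.43,26.84,70.56,83.90,49.14,35.52
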