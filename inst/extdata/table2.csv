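compound,pIC50_exp,pIC50_pred,pIC50_loocv,is_test
1,7.00,7.11,7.17,0
2,7.20,7.30,,1
3,7.35,7.36,7.33,0
4,7.33,7.23,7.16,0
5,7.01,7.00,,1
6,7.14,7.04,6.92,0
7,7.14,7.03,6.84,0
8,6.71,7.01,7.14,0
9,6.64,6.80,,1
10,7.06,7.13,7.14,0
11,6.91,7.01,7.28,0
12,6.62,6.73,6.89,0
13,6.60,6.70,6.78,0
14,6.85,6.73,,1
15,6.67,6.70,6.70,0
16,6.60,6.70,6.70,0
17,6.94,6.86,6.86,0
18,6.74,6.79,6.79,0
19,6.52,6.73,,1
20,8.70,8.27,8.18,0
21,8.30,8.34,8.34,0
22,7.46,7.39,7.39,0
23,7.40,7.50,7.43,0
24,8.22,8.24,,1
25,8.15,8.25,8.57,0
26,8.30,8.24,8.25,0
27,8.05,8.13,8.14,0
28,8.22,8.11,8.05,0
29,8.15,8.05,7.90,0
30,8.00,7.78,,1
31,7.66,7.77,8.11,0
32,8.15,7.80,,1
33,7.82,7.93,8.17,0
34,7.77,7.54,,1
35,7.51,7.46,,1
36,8.10,8.00,7.85,0
37,7.72,7.82,8.00,0
38,7.43,7.09,,1
39,7.96,7.93,7.93,0
40,8.10,8.17,8.18,0
41,7.51,7.40,7.30,0
42,7.92,7.89,7.89,0
43,7.51,7.47,7.47,0
44,7.92,7.93,7.93,0
45,7.80,7.70,7.55,0
46,7.60,7.76,7.84,0
47,7.85,7.75,7.26,0
48,7.89,7.98,,1
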