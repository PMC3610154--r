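"n","lower05","upper05","lower01","upper01"
3,1.74492,1.99982,1.73467,1.99999
4,1.91659,2.43935,1.819,2.44742
5,2.08099,2.78241,1.98757,2.81271
6,2.22,3.05619,2.11457,3.11517
7,2.33571,3.28188,2.22017,3.3676
8,2.43301,3.47066,2.30861,3.5847
9,2.51774,3.63306,2.38728,3.77047
10,2.59299,3.77663,2.45853,3.93335
11,2.66149,3.90232,2.52453,4.0766
12,2.72465,4.0149,2.58337,4.20908
13,2.78271,4.11692,2.63753,4.32377
14,2.83488,4.21267,2.68724,4.43048
15,2.88475,4.29417,2.73478,4.5254
16,2.93032,4.37204,2.77724,4.61649
17,2.97469,4.44553,2.81886,4.70117
18,3.01354,4.51198,2.85703,4.77445
19,3.05255,4.57434,2.89439,4.84275
20,3.08941,4.63143,2.92741,4.90938
21,3.12168,4.6853,2.96023,4.96793
22,3.15518,4.73706,2.99203,5.03448
23,3.186,4.78521,3.02105,5.08208
24,3.21801,4.83401,3.05063,5.14094
25,3.24731,4.87492,3.08095,5.18288
26,3.27185,4.91741,3.10723,5.23348
27,3.30018,4.96,3.13368,5.28242
28,3.32445,4.99868,3.15522,5.32207
29,3.34709,5.03084,3.17954,5.35907
30,3.37322,5.06164,3.20268,5.39935
31,3.39682,5.09719,3.22189,5.43142
32,3.41846,5.12683,3.24823,5.46821
33,3.43781,5.16475,3.26651,5.50904
34,3.46007,5.18517,3.28543,5.53378
35,3.48068,5.21803,3.30323,5.57602
36,3.50007,5.24372,3.32506,5.59775
37,3.52091,5.27214,3.3455,5.6318
38,3.53946,5.29346,3.36364,5.65621
39,3.5561,5.32278,3.37776,5.68902
40,3.57498,5.34182,3.40074,5.70655
41,3.59155,5.3661,3.41411,5.73507
42,3.60789,5.3898,3.43201,5.76193
43,3.62413,5.41247,3.44624,5.78682
44,3.64049,5.43319,3.46154,5.81339
45,3.65413,5.45168,3.47232,5.82008
46,3.67204,5.47231,3.49336,5.8502
47,3.68709,5.49233,3.50607,5.87903
48,3.70083,5.51314,3.51988,5.89368
49,3.71697,5.53265,3.53695,5.91267
50,3.72989,5.54336,3.55044,5.92608
51,3.74447,5.56449,3.56209,5.94998
52,3.75545,5.57785,3.57497,5.96845
53,3.77077,5.59727,3.58839,5.98928
54,3.78277,5.61615,3.60154,6.00656
55,3.79574,5.63191,3.61117,6.02938
56,3.80829,5.64372,3.62556,6.04437
57,3.82172,5.65457,3.64091,6.04713
58,3.83251,5.67616,3.64786,6.07369
59,3.84374,5.68877,3.66152,6.09239
60,3.85746,5.70243,3.67552,6.09898
61,3.86559,5.7173,3.68141,6.11843
62,3.87894,5.7281,3.69485,6.12947
63,3.88901,5.74517,3.70279,6.14996
64,3.90189,5.75889,3.71931,6.16128
65,3.91153,5.772,3.72622,6.17942
66,3.91961,5.78083,3.73686,6.18902
67,3.9321,5.7963,3.7493,6.1994
68,3.94087,5.80803,3.7579,6.21146
69,3.95301,5.81775,3.76929,6.22385
70,3.96196,5.82696,3.77562,6.23713
71,3.96978,5.8435,3.78337,6.25235
72,3.97947,5.85586,3.79192,6.26683
73,3.99022,5.86354,3.80359,6.27352
74,4.00153,5.87652,3.81373,6.28141
75,4.00771,5.88507,3.82322,6.29909
76,4.01781,5.89631,3.8336,6.31365
77,4.02663,5.90696,3.84051,6.31948
78,4.03541,5.91669,3.84718,6.33255
79,4.04604,5.92273,3.86054,6.34196
80,4.05189,5.93534,3.86599,6.35959
81,4.06157,5.94605,3.8729,6.36828
82,4.06738,5.95781,3.88037,6.37028
83,4.07741,5.96797,3.89216,6.38522
84,4.08549,5.97396,3.89906,6.40674
85,4.09352,5.98891,3.90493,6.41042
86,4.10089,5.99793,3.91496,6.41526
87,4.11289,6.00151,3.92455,6.42411
88,4.11986,6.01015,3.93402,6.42813
89,4.12511,6.0229,3.93782,6.44221
90,4.13277,6.02686,3.94945,6.45872
91,4.14006,6.03773,3.95221,6.45325
92,4.1466,6.04982,3.95807,6.46805
93,4.15323,6.05676,3.96849,6.48334
94,4.16139,6.06161,3.97624,6.48265
95,4.17153,6.07044,3.98522,6.49191
96,4.17669,6.07625,3.98815,6.49477
97,4.18417,6.08593,3.99784,6.50873
98,4.19126,6.09168,4.00171,6.511
99,4.19724,6.1022,4.00813,6.52778
100,4.20364,6.11088,4.0171,6.53718
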