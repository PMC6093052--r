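position,label,tfc,tfc_sd,taa,taa_sd
1,1,2.1,0.18,0.47,0.03
2,2,7.35,0.42,0.99,0.05
3,3,10.16,0.76,1.93,0.12
4,4,13.53,0.87,2.12,0.16
5,5,46.57,3.25,3.48,0.27
6,6,15.15,0.93,2.33,0.13
7,7,21.96,1.98,2.67,0.15
8,8,13.41,1.15,1.52,0.1
9,9,7.16,0.63,1.51,0.11
10,10,29.21,1.92,2.45,0.15
11,11,19.84,1.82,2.34,0.14
12,12,25.96,2.29,2.83,0.18
13,13,26.84,2.32,2.59,0.19
14,14,19.53,1.75,1.82,0.12
15,15,20.46,1.69,2.08,0.18
16,16,33.96,2.98,3.26,0.26
17,17,29.02,1.92,2.33,0.16
18,16,48.82,3.44,4.42,0.32
19,19,31.52,2.76,2.6,0.16
20,20,22.9,1.54,2.04,0.18
21,21,24.9,1.59,2.67,0.21
22,22,29.4,1.97,2.96,0.13
23,23,17.9,0.98,1.61,0.09
24,24,21.84,1.89,2.57,0.19
25,25,49.2,2.92,4.65,0.25
26,26,11.41,0.7,1.19,0.09
27,27,19.21,1.06,1.8,0.12
28,28,22.84,1.42,2.93,0.15
29,29,20.78,1.39,2.5,0.16
30,30,28.71,2.35,3.41,0.21
31,31,16.97,1.04,1.65,0.09
32,32,14.97,0.78,1.32,0.09
33,33,26.77,1.85,2.99,0.17
34,34,7.1,0.55,0.81,0.06
35,35,18.15,1.07,2.63,0.17
36,36,14.53,0.96,1.39,0.1
37,37,29.02,2.14,3.73,0.21
38,38,15.97,0.98,1.28,0.09
39,39,24.02,1.4,2.11,0.11
40,40,23.59,1.79,2.98,0.19
41,41,7.97,0.48,1.06,0.06
42,42,10.72,0.98,1.14,0.08
43,43,43.33,3.16,3.97,0.21
44,44,9.91,0.69,1.19,0.09
45,45,9.28,0.64,1.75,0.12
46,46,8.6,0.63,1.0,0.09
47,47,49.13,2.67,3.84,0.24
48,48,14.53,0.93,1.99,0.11
49,49,14.15,0.96,1.47,0.08
50,50,19.4,1.65,2.51,0.16
51,51,17.4,1.34,1.68,0.1
52,52,23.77,1.87,2.69,0.19
53,53,17.65,0.95,1.99,0.12
54,54,11.47,0.73,1.19,0.09
55,55,30.77,1.98,3.15,0.23
56,56,30.71,1.85,2.84,0.22
57,57,35.89,2.45,3.18,0.25
58,58,36.14,2.24,3.5,0.18
59,59,43.45,2.89,3.57,0.27
60,60,14.22,1.07,1.47,0.09
61,61,22.96,1.48,2.64,0.14
62,62,36.02,1.91,3.59,0.23
63,63,21.15,1.58,2.62,0.19
64,64,37.33,2.68,3.78,0.27
65,65,19.53,1.39,1.72,0.11
66,66,3.79,0.27,0.71,0.05
67,67,25.02,1.52,2.07,0.13
68,68,28.65,1.86,2.31,0.16
69,69,20.34,1.53,2.17,0.18
70,70,28.33,1.94,2.19,0.17
71,71,25.77,2.05,2.42,0.21
72,72,20.53,1.86,2.18,0.19
73,73,6.41,0.51,0.88,0.05
74,74,15.53,1.27,1.46,0.09
75,75,22.15,1.75,2.28,0.16
76,76,8.35,0.61,1.09,0.07
77,77,30.08,1.98,3.0,0.19
78,78,32.27,2.21,3.35,0.21
79,79,7.22,0.46,1.01,0.07
80,80,15.59,0.95,1.96,0.16
81,81,7.66,0.68,1.64,0.12
82,82,13.59,0.97,1.93,0.13
83,83,21.46,1.46,2.94,0.21
84,84,9.1,0.54,0.83,0.06
85,85,7.16,0.58,0.57,0.03
86,86,16.78,1.07,1.24,0.1
87,87,16.09,0.99,1.39,0.09
88,88,24.09,1.54,2.81,0.18
89,89,18.4,1.48,1.68,0.12
90,90,20.71,1.35,2.79,0.22
91,91,19.65,1.28,2.62,0.21
92,92,18.71,1.23,1.66,0.11
93,93,18.21,1.01,2.23,0.15
94,94,18.9,1.42,2.18,0.18
95,95,16.15,0.97,1.6,0.12
96,96,18.9,1.12,2.78,0.15
97,97,17.9,1.53,2.91,0.19
98,98,11.97,0.98,1.22,0.08
99,99,4.41,0.35,0.72,0.06
100,100,2.72,0.17,0.32,0.22
101,101,3.6,0.23,0.52,0.03
102,102,6.03,0.51,0.84,0.06
103,103,8.53,0.64,1.4,0.08
104,104,4.72,0.36,0.55,0.04
105,105,7.78,0.42,1.35,0.08
106,106,1.85,0.12,0.97,0.09
107,107,7.16,0.58,1.91,0.11
108,108,8.72,0.63,2.41,0.15
109,109,6.16,0.51,0.55,0.03
110,110,1.47,0.93,0.24,0.02
111,111,14.78,0.54,2.81,0.18
112,112,8.91,0.61,1.42,0.09
113,113,11.97,0.85,2.42,0.15
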