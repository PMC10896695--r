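"frame","t","intensity"
0,0,78
1,0.0333333333333333,78
2,0.0666666666666667,78
3,0.1,78
4,0.133333333333333,78
5,0.166666666666667,78
6,0.2,78
7,0.233333333333333,78
8,0.266666666666667,78
9,0.3,78
10,0.333333333333333,78
11,0.366666666666667,78
12,0.4,78
13,0.433333333333333,78
14,0.466666666666667,78
15,0.5,78
16,0.533333333333333,78
17,0.566666666666667,78
18,0.6,78
19,0.633333333333333,78
20,0.666666666666667,78
21,0.7,78
22,0.733333333333333,78
23,0.766666666666667,78
24,0.8,78
25,0.833333333333333,78
26,0.866666666666667,78
27,0.9,78
28,0.933333333333333,78
29,0.966666666666667,78
30,1,78
31,1.03333333333333,78
32,1.06666666666667,78
33,1.1,78
34,1.13333333333333,78
35,1.16666666666667,78
36,1.2,78
37,1.23333333333333,78
38,1.26666666666667,78
39,1.3,78
40,1.33333333333333,78
41,1.36666666666667,78
42,1.4,78
43,1.43333333333333,78
44,1.46666666666667,78
45,1.5,78
46,1.53333333333333,78
47,1.56666666666667,78
48,1.6,78
49,1.63333333333333,78
50,1.66666666666667,52
51,1.7,52
52,1.73333333333333,52
53,1.76666666666667,52
54,1.8,52
55,1.83333333333333,52
56,1.86666666666667,52
57,1.9,52
58,1.93333333333333,52
59,1.96666666666667,52
60,2,52
61,2.03333333333333,52
62,2.06666666666667,52
63,2.1,52
64,2.13333333333333,52
65,2.16666666666667,52
66,2.2,52
67,2.23333333333333,52
68,2.26666666666667,52
69,2.3,52
70,2.33333333333333,52
71,2.36666666666667,52
72,2.4,52
73,2.43333333333333,52
74,2.46666666666667,52
75,2.5,52
76,2.53333333333333,52
77,2.56666666666667,52
78,2.6,52
79,2.63333333333333,52
80,2.66666666666667,52
81,2.7,52
82,2.73333333333333,52
83,2.76666666666667,52
84,2.8,52
85,2.83333333333333,52
86,2.86666666666667,52
87,2.9,52
88,2.93333333333333,52
89,2.96666666666667,52
90,3,52
91,3.03333333333333,52
92,3.06666666666667,52
93,3.1,52
94,3.13333333333333,52
95,3.16666666666667,52
96,3.2,52
97,3.23333333333333,52
98,3.26666666666667,52
99,3.3,52
100,3.33333333333333,26
101,3.36666666666667,26
102,3.4,26
103,3.43333333333333,26
104,3.46666666666667,26
105,3.5,26
106,3.53333333333333,26
107,3.56666666666667,26
108,3.6,26
109,3.63333333333333,26
110,3.66666666666667,26
111,3.7,26
112,3.73333333333333,26
113,3.76666666666667,26
114,3.8,26
115,3.83333333333333,26
116,3.86666666666667,26
117,3.9,26
118,3.93333333333333,26
119,3.96666666666667,26
120,4,26
121,4.03333333333333,26
122,4.06666666666667,26
123,4.1,26
124,4.13333333333333,26
125,4.16666666666667,26
126,4.2,26
127,4.23333333333333,26
128,4.26666666666667,26
129,4.3,26
130,4.33333333333333,26
131,4.36666666666667,26
132,4.4,26
133,4.43333333333333,26
134,4.46666666666667,26
135,4.5,26
136,4.53333333333333,26
137,4.56666666666667,26
138,4.6,26
139,4.63333333333333,26
140,4.66666666666667,26
141,4.7,26
142,4.73333333333333,26
143,4.76666666666667,26
144,4.8,26
145,4.83333333333333,26
146,4.86666666666667,26
147,4.9,26
148,4.93333333333333,26
149,4.96666666666667,26
150,5,0
151,5.03333333333333,0
152,5.06666666666667,0
153,5.1,0
154,5.13333333333333,0
155,5.16666666666667,0
156,5.2,0
157,5.23333333333333,0
158,5.26666666666667,0
159,5.3,0
160,5.33333333333333,0
161,5.36666666666667,0
162,5.4,0
163,5.43333333333333,0
164,5.46666666666667,0
165,5.5,0
166,5.53333333333333,0
167,5.56666666666667,0
168,5.6,0
169,5.63333333333333,0
170,5.66666666666667,0
171,5.7,0
172,5.73333333333333,0
173,5.76666666666667,0
174,5.8,0
175,5.83333333333333,0
176,5.86666666666667,0
177,5.9,0
178,5.93333333333333,0
179,5.96666666666667,0
180,6,0
181,6.03333333333333,0
182,6.06666666666667,0
183,6.1,0
184,6.13333333333333,0
185,6.16666666666667,0
186,6.2,0
187,6.23333333333333,0
188,6.26666666666667,0
189,6.3,0
190,6.33333333333333,0
191,6.36666666666667,0
192,6.4,0
193,6.43333333333333,0
194,6.46666666666667,0
195,6.5,0
196,6.53333333333333,0
197,6.56666666666667,0
198,6.6,0
199,6.63333333333333,0
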