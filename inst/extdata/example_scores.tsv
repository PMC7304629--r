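position	residue	score
1	T	0.476827
2	C	0.532097
3	A	0.477960
4	I	0.483526
5	D	0.524189
6	W	0.515808
7	T	0.478007
8	P	0.491571
9	E	0.495129
10	D	0.493252
11	C	0.467082
12	F	0.542241
13	V	0.480995
14	W	0.458367
15	P	0.462285
16	N	0.512360
17	H	0.494229
18	D	0.473158
19	C	0.505221
20	M	0.463100
21	C	0.497212
22	V	0.491064
23	R	0.529606
24	G	0.480016
25	N	0.489911
26	A	0.540804
27	I	0.473559
28	L	0.529591
29	P	0.507880
30	G	0.547146
31	W	0.197840
32	G	0.191562
33	V	0.233534
34	F	0.223285
35	V	0.216766
36	K	0.146768
37	W	0.198125
38	F	0.202246
39	F	0.193705
40	W	0.192292
41	C	0.176528
42	L	0.196049
43	Q	0.465236
44	R	0.493540
45	V	0.526822
46	N	0.503851
47	R	0.480488
48	Q	0.498782
49	I	0.533194
50	G	0.498520
51	C	0.507842
52	A	0.541037
53	T	0.504170
54	E	0.528810
55	D	0.488811
56	M	0.490760
57	I	0.474864
58	H	0.536627
59	K	0.475308
60	V	0.519061
61	H	0.498499
62	L	0.488351
63	N	0.518199
64	S	0.535904
65	C	0.472695
66	F	0.501244
67	C	0.485191
68	R	0.499536
69	W	0.526443
70	T	0.471294
71	W	0.500664
72	C	0.495899
73	F	0.475254
74	G	0.487438
75	G	0.494200
76	D	0.504117
77	D	0.511769
78	E	0.479513
79	I	0.515301
80	W	0.468913
81	I	0.701048
82	K	0.719583
83	E	0.672745
84	E	0.693658
85	H	0.702623
86	P	0.704199
87	C	0.674325
88	P	0.659246
89	H	0.686936
90	D	0.701056
91	R	0.730194
92	A	0.723087
93	F	0.498276
94	C	0.517390
95	H	0.469226
96	S	0.494770
97	L	0.508212
98	I	0.489908
99	I	0.508940
100	A	0.520366
101	Y	0.471770
102	T	0.470908
103	F	0.507168
104	F	0.482350
105	P	0.521789
106	Q	0.440369
107	P	0.533236
108	L	0.498175
109	C	0.526336
110	S	0.515844
111	T	0.503887
112	T	0.477679
113	W	0.497494
114	R	0.486419
115	Q	0.466837
116	Q	0.499206
117	Q	0.495772
118	V	0.481942
119	P	0.489807
120	R	0.463180
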