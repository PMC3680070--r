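stratum	setting	polarity	size	kernel	r	observed	e	ratio_e	ratio_size
ND	CV	negative	521	edit	18.1	305	427	0.71	0.59
ND	CV	negative	521	lexical	25	203	391	0.52	0.39
ND	CV	negative	521	SST	26.6	186	382	0.49	0.36
ND	CV	negative	521	APG	25.3	185	389	0.48	0.36
ND	CV	negative	521	PT	27.9	185	376	0.49	0.36
ND	CV	negative	521	syntactic	24.4	180	394	0.46	0.35
ND	CV	negative	521	cosine	24.9	168	391	0.43	0.32
ND	CV	negative	521	ST	28	160	375	0.43	0.3
ND	CV	negative	521	shallow	24.6	136	393	0.35	0.26
ND	CV	negative	521	kBSPS	36.6	122	330	0.37	0.23
ND	CV	negative	521	combined	24.8	117	392	0.3	0.22
ND	CV	negative	521	SL	30.4	116	363	0.32	0.22
ND	CV	negative	521	SpT	46.4	88	279	0.32	0.17
ND	CL	negative	521	SST	26.9	288	381	0.76	0.55
ND	CL	negative	521	edit	22.5	279	404	0.69	0.54
ND	CL	negative	521	ST	29.2	231	369	0.63	0.44
ND	CL	negative	521	APG	26.9	207	381	0.54	0.4
ND	CL	negative	521	SL	29.9	177	365	0.48	0.34
ND	CL	negative	521	lexical	24.5	170	393	0.43	0.33
ND	CL	negative	521	cosine	26.6	157	382	0.41	0.3
ND	CL	negative	521	syntactic	26.9	155	381	0.41	0.3
ND	CL	negative	521	SpT	42.1	142	302	0.47	0.27
ND	CL	negative	521	combined	26.8	132	381	0.35	0.25
ND	CL	negative	521	shallow	28.6	127	372	0.34	0.24
ND	CL	negative	521	kBSPS	37.1	120	328	0.37	0.23
PD	CV	positive	190	SpT	46.4	71	88	0.81	0.37
PD	CV	positive	190	PT	27.9	33	53	0.62	0.17
PD	CV	positive	190	kBSPS	36.6	22	70	0.31	0.12
PD	CV	positive	190	ST	28	19	53	0.36	0.1
PD	CV	positive	190	SST	26.6	16	51	0.31	0.08
PD	CV	positive	190	APG	25.3	15	48	0.31	0.08
PD	CV	positive	190	SL	30.4	15	58	0.26	0.08
PD	CV	positive	190	syntactic	24.4	14	46	0.3	0.07
PD	CV	positive	190	edit	18.1	11	34	0.32	0.06
PD	CV	positive	190	lexical	25	9	47	0.19	0.05
PD	CV	positive	190	shallow	24.6	7	47	0.15	0.04
PD	CV	positive	190	cosine	24.9	7	47	0.15	0.04
PD	CV	positive	190	combined	24.8	4	47	0.09	0.02
PD	CL	positive	190	SpT	42.1	53	80	0.66	0.28
PD	CL	positive	190	SST	26.9	39	51	0.76	0.21
PD	CL	positive	190	ST	29.2	28	55	0.51	0.15
PD	CL	positive	190	SL	29.9	27	57	0.47	0.14
PD	CL	positive	190	combined	26.8	16	51	0.31	0.08
PD	CL	positive	190	shallow	28.6	14	54	0.26	0.07
PD	CL	positive	190	kBSPS	37.1	14	70	0.2	0.07
PD	CL	positive	190	APG	26.9	9	51	0.18	0.05
PD	CL	positive	190	edit	22.5	7	43	0.16	0.04
PD	CL	positive	190	cosine	26.6	4	51	0.08	0.02
PD	CL	positive	190	syntactic	26.9	2	51	0.04	0.01
PD	CL	positive	190	lexical	24.5	1	47	0.02	0.01
NE	CV	negative	1510	APG	25.3	1510	1129	NA	NA
NE	CV	negative	1510	cosine	24.9	1510	1134	NA	NA
NE	CV	negative	1510	edit	18.1	1510	1237	NA	NA
NE	CV	negative	1510	combined	24.8	1510	1135	NA	NA
NE	CV	negative	1510	shallow	24.6	1510	1138	NA	NA
NE	CV	negative	1510	syntactic	24.4	1510	1142	NA	NA
NE	CV	negative	1510	kBSPS	36.6	1509	957	NA	NA
NE	CV	negative	1510	SL	30.4	1508	1051	NA	NA
NE	CV	negative	1510	lexical	25	1506	1133	NA	NA
NE	CV	negative	1510	PT	27.9	1505	1089	NA	NA
NE	CV	negative	1510	ST	28	1502	1088	NA	NA
NE	CV	negative	1510	SST	26.6	1501	1108	NA	NA
NE	CV	negative	1510	SpT	46.4	1484	810	NA	NA
NE	CL	negative	1510	shallow	28.6	1510	1078	NA	NA
NE	CL	negative	1510	combined	26.8	1505	1105	NA	NA
NE	CL	negative	1510	APG	26.9	1504	1104	NA	NA
NE	CL	negative	1510	SL	29.9	1504	1059	NA	NA
NE	CL	negative	1510	lexical	24.5	1501	1140	NA	NA
NE	CL	negative	1510	kBSPS	37.1	1494	950	NA	NA
NE	CL	negative	1510	edit	22.5	1491	1171	NA	NA
NE	CL	negative	1510	cosine	26.6	1490	1109	NA	NA
NE	CL	negative	1510	ST	29.2	1489	1069	NA	NA
NE	CL	negative	1510	SST	26.9	1484	1104	NA	NA
NE	CL	negative	1510	syntactic	26.9	1483	1103	NA	NA
NE	CL	negative	1510	SpT	42.1	1429	874	NA	NA
PE	CV	positive	219	combined	24.8	218	54	NA	NA
PE	CV	positive	219	APG	25.3	218	55	NA	NA
PE	CV	positive	219	SpT	46.4	218	102	NA	NA
PE	CV	positive	219	kBSPS	36.6	217	80	NA	NA
PE	CV	positive	219	SL	30.4	216	67	NA	NA
PE	CV	positive	219	shallow	24.6	213	54	NA	NA
PE	CV	positive	219	PT	27.9	210	61	NA	NA
PE	CV	positive	219	syntactic	24.4	208	53	NA	NA
PE	CV	positive	219	cosine	24.9	206	55	NA	NA
PE	CV	positive	219	ST	28	205	61	NA	NA
PE	CV	positive	219	lexical	25	204	55	NA	NA
PE	CV	positive	219	SST	26.6	201	58	NA	NA
PE	CV	positive	219	edit	18.1	192	40	NA	NA
PE	CL	positive	219	kBSPS	37.1	218	81	NA	NA
PE	CL	positive	219	combined	26.8	217	59	NA	NA
PE	CL	positive	219	shallow	28.6	205	63	NA	NA
PE	CL	positive	219	SL	29.9	202	65	NA	NA
PE	CL	positive	219	syntactic	26.9	202	59	NA	NA
PE	CL	positive	219	lexical	24.5	196	54	NA	NA
PE	CL	positive	219	APG	26.9	194	59	NA	NA
PE	CL	positive	219	cosine	26.6	181	58	NA	NA
PE	CL	positive	219	SpT	42.1	177	92	NA	NA
PE	CL	positive	219	edit	22.5	154	49	NA	NA
PE	CL	positive	219	ST	29.2	126	64	NA	NA
PE	CL	positive	219	SST	26.9	123	59	NA	NA
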