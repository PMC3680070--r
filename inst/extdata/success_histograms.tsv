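corpus	setting	level	total	positive	negative
AIMed	CV	0	77	73	4
AIMed	CV	1	95	89	6
AIMed	CV	2	105	101	4
AIMed	CV	3	121	104	17
AIMed	CV	4	139	115	24
AIMed	CV	5	140	91	49
AIMed	CV	6	142	70	72
AIMed	CV	7	176	65	111
AIMed	CV	8	248	72	176
AIMed	CV	9	372	69	303
AIMed	CV	10	461	47	414
AIMed	CV	11	619	29	590
AIMed	CV	12	1002	43	959
AIMed	CV	13	2137	32	2105
BioInfer	CV	0	58	44	14
BioInfer	CV	1	158	107	51
BioInfer	CV	2	206	130	76
BioInfer	CV	3	306	198	108
BioInfer	CV	4	349	203	146
BioInfer	CV	5	440	225	215
BioInfer	CV	6	481	209	272
BioInfer	CV	7	619	248	371
BioInfer	CV	8	785	256	529
BioInfer	CV	9	876	245	631
BioInfer	CV	10	1067	204	863
BioInfer	CV	11	1061	164	897
BioInfer	CV	12	1390	183	1207
BioInfer	CV	13	1870	118	1752
HPRD50	CV	0	4	1	3
HPRD50	CV	1	7	4	3
HPRD50	CV	2	12	8	4
HPRD50	CV	3	18	7	11
HPRD50	CV	4	26	10	16
HPRD50	CV	5	20	12	8
HPRD50	CV	6	33	9	24
HPRD50	CV	7	35	15	20
HPRD50	CV	8	37	9	28
HPRD50	CV	9	46	10	36
HPRD50	CV	10	61	33	28
HPRD50	CV	11	49	19	30
HPRD50	CV	12	57	13	44
HPRD50	CV	13	28	13	15
IEPA	CV	0	2	1	1
IEPA	CV	1	13	5	8
IEPA	CV	2	11	3	8
IEPA	CV	3	26	13	13
IEPA	CV	4	30	10	20
IEPA	CV	5	43	19	24
IEPA	CV	6	61	22	39
IEPA	CV	7	51	20	31
IEPA	CV	8	79	31	48
IEPA	CV	9	99	32	67
IEPA	CV	10	101	38	63
IEPA	CV	11	112	46	66
IEPA	CV	12	106	47	59
IEPA	CV	13	83	48	35
LLL	CV	0	5	0	5
LLL	CV	1	7	0	7
LLL	CV	2	27	0	27
LLL	CV	3	10	0	10
LLL	CV	4	16	0	16
LLL	CV	5	21	2	19
LLL	CV	6	26	1	25
LLL	CV	7	29	8	21
LLL	CV	8	19	6	13
LLL	CV	9	26	15	11
LLL	CV	10	31	19	12
LLL	CV	11	32	32	0
LLL	CV	12	45	45	0
LLL	CV	13	36	36	0
AIMed	CL	0	41	0	41
AIMed	CL	1	73	6	67
AIMed	CL	2	199	26	173
AIMed	CL	3	315	39	276
AIMed	CL	4	489	71	418
AIMed	CL	5	606	84	522
AIMed	CL	6	547	94	453
AIMed	CL	7	725	136	589
AIMed	CL	8	721	132	589
AIMed	CL	9	767	110	657
AIMed	CL	10	574	118	456
AIMed	CL	11	414	69	345
AIMed	CL	12	363	115	248
BioInfer	CL	0	319	319	0
BioInfer	CL	1	362	362	0
BioInfer	CL	2	322	312	10
BioInfer	CL	3	303	280	23
BioInfer	CL	4	321	260	61
BioInfer	CL	5	355	239	116
BioInfer	CL	6	400	208	192
BioInfer	CL	7	432	190	242
BioInfer	CL	8	586	146	440
BioInfer	CL	9	737	95	642
BioInfer	CL	10	1060	79	981
BioInfer	CL	11	1906	29	1877
BioInfer	CL	12	2563	15	2548
HPRD50	CL	0	1	0	1
HPRD50	CL	1	4	2	2
HPRD50	CL	2	7	3	4
HPRD50	CL	3	23	10	13
HPRD50	CL	4	27	15	12
HPRD50	CL	5	27	15	12
HPRD50	CL	6	41	22	19
HPRD50	CL	7	43	18	25
HPRD50	CL	8	52	17	35
HPRD50	CL	9	61	18	43
HPRD50	CL	10	50	14	36
HPRD50	CL	11	52	16	36
HPRD50	CL	12	45	13	32
IEPA	CL	0	9	9	0
IEPA	CL	1	19	17	2
IEPA	CL	2	33	32	1
IEPA	CL	3	38	36	2
IEPA	CL	4	48	45	3
IEPA	CL	5	44	32	12
IEPA	CL	6	51	34	17
IEPA	CL	7	63	32	31
IEPA	CL	8	69	35	34
IEPA	CL	9	107	36	71
IEPA	CL	10	110	13	97
IEPA	CL	11	131	6	125
IEPA	CL	12	95	8	87
LLL	CL	0	3	3	0
LLL	CL	1	5	4	1
LLL	CL	2	10	9	1
LLL	CL	3	19	19	0
LLL	CL	4	25	25	0
LLL	CL	5	25	20	5
LLL	CL	6	26	18	8
LLL	CL	7	20	7	13
LLL	CL	8	34	18	16
LLL	CL	9	34	19	15
LLL	CL	10	56	8	48
LLL	CL	11	50	12	38
LLL	CL	12	23	2	21
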