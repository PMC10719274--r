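node_id	label	volume_mm3
0	PreCG.L	24227
1	PreCG.R	6453
2	SFGdor.L	11437
3	SFGdor.R	13616
4	ORBsup.L	10859
5	ORBsup.R	5781
6	MFG.L	3707
7	MFG.R	13025
8	ORBmid.L	6191
9	ORBmid.R	8246
10	IFGoperc.L	4866
11	IFGoperc.R	5679
12	IFGtriang.L	11207
13	IFGtriang.R	15524
14	ORBinf.L	11995
15	ORBinf.R	6995
16	ROL.L	12555
17	ROL.R	3976
18	SMA.L	18014
19	SMA.R	8772
20	OLF.L	10250
21	OLF.R	5802
22	SFGmed.L	8312
23	SFGmed.R	8223
24	ORBsupmed.L	8513
25	ORBsupmed.R	13518
26	REC.L	4608
27	REC.R	23603
28	INS.L	3816
29	INS.R	12484
30	ACG.L	4111
31	ACG.R	5175
32	DCG.L	17229
33	DCG.R	10961
34	PCG.L	4916
35	PCG.R	14927
36	HIP.L	4460
37	HIP.R	4856
38	PHG.L	30000
39	PHG.R	6073
40	AMYG.L	8009
41	AMYG.R	7080
42	CAL.L	23182
43	CAL.R	7475
44	CUN.L	5338
45	CUN.R	6048
46	LING.L	20008
47	LING.R	7748
48	SOG.L	9175
49	SOG.R	9303
50	MOG.L	12945
51	MOG.R	8098
52	IOG.L	6337
53	IOG.R	9943
54	FFG.L	20811
55	FFG.R	20994
56	PoCG.L	8095
57	PoCG.R	7961
58	SPG.L	17224
59	SPG.R	8313
60	IPL.L	5730
61	IPL.R	10854
62	SMG.L	12079
63	SMG.R	12432
64	ANG.L	4996
65	ANG.R	8698
66	PCUN.L	9882
67	PCUN.R	9298
68	PCL.L	13564
69	PCL.R	21494
70	CAU.L	15682
71	CAU.R	5819
72	PUT.L	23059
73	PUT.R	11201
74	PAL.L	6926
75	PAL.R	9485
76	THA.L	9085
77	THA.R	8453
78	HES.L	9701
79	HES.R	7892
80	STG.L	7423
81	STG.R	11980
82	TPOsup.L	5459
83	TPOsup.R	20072
84	MTG.L	12693
85	MTG.R	5558
86	TPOmid.L	15114
87	TPOmid.R	4757
88	ITG.L	10431
89	ITG.R	2983
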