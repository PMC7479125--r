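region_id	region_name	hemisphere	homologue_id
1	PreCG	L	46
2	SFGdor	L	47
3	ORBsup	L	48
4	MFG	L	49
5	ORBmid	L	50
6	IFGoperc	L	51
7	IFGtriang	L	52
8	ORBinf	L	53
9	ROL	L	54
10	SMA	L	55
11	OLF	L	56
12	SFGmed	L	57
13	ORBsupmed	L	58
14	REC	L	59
15	INS	L	60
16	ACG	L	61
17	DCG	L	62
18	PCG	L	63
19	HIP	L	64
20	PHG	L	65
21	AMYG	L	66
22	CAL	L	67
23	CUN	L	68
24	LING	L	69
25	SOG	L	70
26	MOG	L	71
27	IOG	L	72
28	FFG	L	73
29	PoCG	L	74
30	SPG	L	75
31	IPL	L	76
32	SMG	L	77
33	ANG	L	78
34	PCUN	L	79
35	PCL	L	80
36	CAU	L	81
37	PUT	L	82
38	PAL	L	83
39	THA	L	84
40	HES	L	85
41	STG	L	86
42	TPOsup	L	87
43	MTG	L	88
44	TPOmid	L	89
45	ITG	L	90
46	PreCG	R	1
47	SFGdor	R	2
48	ORBsup	R	3
49	MFG	R	4
50	ORBmid	R	5
51	IFGoperc	R	6
52	IFGtriang	R	7
53	ORBinf	R	8
54	ROL	R	9
55	SMA	R	10
56	OLF	R	11
57	SFGmed	R	12
58	ORBsupmed	R	13
59	REC	R	14
60	INS	R	15
61	ACG	R	16
62	DCG	R	17
63	PCG	R	18
64	HIP	R	19
65	PHG	R	20
66	AMYG	R	21
67	CAL	R	22
68	CUN	R	23
69	LING	R	24
70	SOG	R	25
71	MOG	R	26
72	IOG	R	27
73	FFG	R	28
74	PoCG	R	29
75	SPG	R	30
76	IPL	R	31
77	SMG	R	32
78	ANG	R	33
79	PCUN	R	34
80	PCL	R	35
81	CAU	R	36
82	PUT	R	37
83	PAL	R	38
84	THA	R	39
85	HES	R	40
86	STG	R	41
87	TPOsup	R	42
88	MTG	R	43
89	TPOmid	R	44
90	ITG	R	45
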