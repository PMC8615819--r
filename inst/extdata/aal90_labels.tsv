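index	name	abbreviation
1	Precentral_L	PreCG.L
2	Precentral_R	PreCG.R
3	Frontal_Sup_L	SFGdor.L
4	Frontal_Sup_R	SFGdor.R
5	Frontal_Sup_Orb_L	ORBsup.L
6	Frontal_Sup_Orb_R	ORBsup.R
7	Frontal_Mid_L	MFG.L
8	Frontal_Mid_R	MFG.R
9	Frontal_Mid_Orb_L	ORBmid.L
10	Frontal_Mid_Orb_R	ORBmid.R
11	Frontal_Inf_Oper_L	IFGoperc.L
12	Frontal_Inf_Oper_R	IFGoperc.R
13	Frontal_Inf_Tri_L	IFGtriang.L
14	Frontal_Inf_Tri_R	IFGtriang.R
15	Frontal_Inf_Orb_L	ORBinf.L
16	Frontal_Inf_Orb_R	ORBinf.R
17	Rolandic_Oper_L	ROL.L
18	Rolandic_Oper_R	ROL.R
19	Supp_Motor_Area_L	SMA.L
20	Supp_Motor_Area_R	SMA.R
21	Olfactory_L	OLF.L
22	Olfactory_R	OLF.R
23	Frontal_Sup_Medial_L	SFGmed.L
24	Frontal_Sup_Medial_R	SFGmed.R
25	Frontal_Med_Orb_L	ORBsupmed.L
26	Frontal_Med_Orb_R	ORBsupmed.R
27	Rectus_L	REC.L
28	Rectus_R	REC.R
29	Insula_L	INS.L
30	Insula_R	INS.R
31	Cingulum_Ant_L	ACG.L
32	Cingulum_Ant_R	ACG.R
33	Cingulum_Mid_L	DCG.L
34	Cingulum_Mid_R	DCG.R
35	Cingulum_Post_L	PCG.L
36	Cingulum_Post_R	PCG.R
37	Hippocampus_L	HIP.L
38	Hippocampus_R	HIP.R
39	ParaHippocampal_L	PHG.L
40	ParaHippocampal_R	PHG.R
41	Amygdala_L	AMYG.L
42	Amygdala_R	AMYG.R
43	Calcarine_L	CAL.L
44	Calcarine_R	CAL.R
45	Cuneus_L	CUN.L
46	Cuneus_R	CUN.R
47	Lingual_L	LING.L
48	Lingual_R	LING.R
49	Occipital_Sup_L	SOG.L
50	Occipital_Sup_R	SOG.R
51	Occipital_Mid_L	MOG.L
52	Occipital_Mid_R	MOG.R
53	Occipital_Inf_L	IOG.L
54	Occipital_Inf_R	IOG.R
55	Fusiform_L	FFG.L
56	Fusiform_R	FFG.R
57	Postcentral_L	PoCG.L
58	Postcentral_R	PoCG.R
59	Parietal_Sup_L	SPG.L
60	Parietal_Sup_R	SPG.R
61	Parietal_Inf_L	IPL.L
62	Parietal_Inf_R	IPL.R
63	SupraMarginal_L	SMG.L
64	SupraMarginal_R	SMG.R
65	Angular_L	ANG.L
66	Angular_R	ANG.R
67	Precuneus_L	PCUN.L
68	Precuneus_R	PCUN.R
69	Paracentral_Lobule_L	PCL.L
70	Paracentral_Lobule_R	PCL.R
71	Caudate_L	CAU.L
72	Caudate_R	CAU.R
73	Putamen_L	PUT.L
74	Putamen_R	PUT.R
75	Pallidum_L	PAL.L
76	Pallidum_R	PAL.R
77	Thalamus_L	THA.L
78	Thalamus_R	THA.R
79	Heschl_L	HES.L
80	Heschl_R	HES.R
81	Temporal_Sup_L	STG.L
82	Temporal_Sup_R	STG.R
83	Temporal_Pole_Sup_L	TPOsup.L
84	Temporal_Pole_Sup_R	TPOsup.R
85	Temporal_Mid_L	MTG.L
86	Temporal_Mid_R	MTG.R
87	Temporal_Pole_Mid_L	TPOmid.L
88	Temporal_Pole_Mid_R	TPOmid.R
89	Temporal_Inf_L	ITG.L
90	Temporal_Inf_R	ITG.R
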