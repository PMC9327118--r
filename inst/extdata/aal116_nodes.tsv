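node_id	name	is_cerebellar_hemispheric	is_vermis	homologue_id
1	Precentral_L	FALSE	FALSE	NA
2	Precentral_R	FALSE	FALSE	NA
3	Frontal_Sup_L	FALSE	FALSE	NA
4	Frontal_Sup_R	FALSE	FALSE	NA
5	Frontal_Sup_Orb_L	FALSE	FALSE	NA
6	Frontal_Sup_Orb_R	FALSE	FALSE	NA
7	Frontal_Mid_L	FALSE	FALSE	NA
8	Frontal_Mid_R	FALSE	FALSE	NA
9	Frontal_Mid_Orb_L	FALSE	FALSE	NA
10	Frontal_Mid_Orb_R	FALSE	FALSE	NA
11	Frontal_Inf_Oper_L	FALSE	FALSE	NA
12	Frontal_Inf_Oper_R	FALSE	FALSE	NA
13	Frontal_Inf_Tri_L	FALSE	FALSE	NA
14	Frontal_Inf_Tri_R	FALSE	FALSE	NA
15	Frontal_Inf_Orb_L	FALSE	FALSE	NA
16	Frontal_Inf_Orb_R	FALSE	FALSE	NA
17	Rolandic_Oper_L	FALSE	FALSE	NA
18	Rolandic_Oper_R	FALSE	FALSE	NA
19	Supp_Motor_Area_L	FALSE	FALSE	NA
20	Supp_Motor_Area_R	FALSE	FALSE	NA
21	Olfactory_L	FALSE	FALSE	NA
22	Olfactory_R	FALSE	FALSE	NA
23	Frontal_Sup_Medial_L	FALSE	FALSE	NA
24	Frontal_Sup_Medial_R	FALSE	FALSE	NA
25	Frontal_Med_Orb_L	FALSE	FALSE	NA
26	Frontal_Med_Orb_R	FALSE	FALSE	NA
27	Rectus_L	FALSE	FALSE	NA
28	Rectus_R	FALSE	FALSE	NA
29	Insula_L	FALSE	FALSE	NA
30	Insula_R	FALSE	FALSE	NA
31	Cingulum_Ant_L	FALSE	FALSE	NA
32	Cingulum_Ant_R	FALSE	FALSE	NA
33	Cingulum_Mid_L	FALSE	FALSE	NA
34	Cingulum_Mid_R	FALSE	FALSE	NA
35	Cingulum_Post_L	FALSE	FALSE	NA
36	Cingulum_Post_R	FALSE	FALSE	NA
37	Hippocampus_L	FALSE	FALSE	NA
38	Hippocampus_R	FALSE	FALSE	NA
39	ParaHippocampal_L	FALSE	FALSE	NA
40	ParaHippocampal_R	FALSE	FALSE	NA
41	Amygdala_L	FALSE	FALSE	NA
42	Amygdala_R	FALSE	FALSE	NA
43	Calcarine_L	FALSE	FALSE	NA
44	Calcarine_R	FALSE	FALSE	NA
45	Cuneus_L	FALSE	FALSE	NA
46	Cuneus_R	FALSE	FALSE	NA
47	Lingual_L	FALSE	FALSE	NA
48	Lingual_R	FALSE	FALSE	NA
49	Occipital_Sup_L	FALSE	FALSE	NA
50	Occipital_Sup_R	FALSE	FALSE	NA
51	Occipital_Mid_L	FALSE	FALSE	NA
52	Occipital_Mid_R	FALSE	FALSE	NA
53	Occipital_Inf_L	FALSE	FALSE	NA
54	Occipital_Inf_R	FALSE	FALSE	NA
55	Fusiform_L	FALSE	FALSE	NA
56	Fusiform_R	FALSE	FALSE	NA
57	Postcentral_L	FALSE	FALSE	NA
58	Postcentral_R	FALSE	FALSE	NA
59	Parietal_Sup_L	FALSE	FALSE	NA
60	Parietal_Sup_R	FALSE	FALSE	NA
61	Parietal_Inf_L	FALSE	FALSE	NA
62	Parietal_Inf_R	FALSE	FALSE	NA
63	SupraMarginal_L	FALSE	FALSE	NA
64	SupraMarginal_R	FALSE	FALSE	NA
65	Angular_L	FALSE	FALSE	NA
66	Angular_R	FALSE	FALSE	NA
67	Precuneus_L	FALSE	FALSE	NA
68	Precuneus_R	FALSE	FALSE	NA
69	Paracentral_Lobule_L	FALSE	FALSE	NA
70	Paracentral_Lobule_R	FALSE	FALSE	NA
71	Caudate_L	FALSE	FALSE	NA
72	Caudate_R	FALSE	FALSE	NA
73	Putamen_L	FALSE	FALSE	NA
74	Putamen_R	FALSE	FALSE	NA
75	Pallidum_L	FALSE	FALSE	NA
76	Pallidum_R	FALSE	FALSE	NA
77	Thalamus_L	FALSE	FALSE	NA
78	Thalamus_R	FALSE	FALSE	NA
79	Heschl_L	FALSE	FALSE	NA
80	Heschl_R	FALSE	FALSE	NA
81	Temporal_Sup_L	FALSE	FALSE	NA
82	Temporal_Sup_R	FALSE	FALSE	NA
83	Temporal_Pole_Sup_L	FALSE	FALSE	NA
84	Temporal_Pole_Sup_R	FALSE	FALSE	NA
85	Temporal_Mid_L	FALSE	FALSE	NA
86	Temporal_Mid_R	FALSE	FALSE	NA
87	Temporal_Pole_Mid_L	FALSE	FALSE	NA
88	Temporal_Pole_Mid_R	FALSE	FALSE	NA
89	Temporal_Inf_L	FALSE	FALSE	NA
90	Temporal_Inf_R	FALSE	FALSE	NA
91	Cerebelum_Crus1_L	TRUE	FALSE	92
92	Cerebelum_Crus1_R	TRUE	FALSE	91
93	Cerebelum_Crus2_L	TRUE	FALSE	94
94	Cerebelum_Crus2_R	TRUE	FALSE	93
95	Cerebelum_3_L	TRUE	FALSE	96
96	Cerebelum_3_R	TRUE	FALSE	95
97	Cerebelum_4_5_L	TRUE	FALSE	98
98	Cerebelum_4_5_R	TRUE	FALSE	97
99	Cerebelum_6_L	TRUE	FALSE	100
100	Cerebelum_6_R	TRUE	FALSE	99
101	Cerebelum_7b_L	TRUE	FALSE	102
102	Cerebelum_7b_R	TRUE	FALSE	101
103	Cerebelum_8_L	TRUE	FALSE	104
104	Cerebelum_8_R	TRUE	FALSE	103
105	Cerebelum_9_L	TRUE	FALSE	106
106	Cerebelum_9_R	TRUE	FALSE	105
107	Cerebelum_10_L	TRUE	FALSE	108
108	Cerebelum_10_R	TRUE	FALSE	107
109	Vermis_1_2	FALSE	TRUE	NA
110	Vermis_3	FALSE	TRUE	NA
111	Vermis_4_5	FALSE	TRUE	NA
112	Vermis_6	FALSE	TRUE	NA
113	Vermis_7	FALSE	TRUE	NA
114	Vermis_8	FALSE	TRUE	NA
115	Vermis_9	FALSE	TRUE	NA
116	Vermis_10	FALSE	TRUE	NA
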