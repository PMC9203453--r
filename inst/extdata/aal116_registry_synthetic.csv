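region_id,name,cx,cy,cz,level2_parent,level1_parent
1,Precentral_L,-34,27,23.7,Frontal_L,Cerebrum_L
2,Precentral_R,42.6,36.8,33.8,Frontal_R,Cerebrum_R
3,Frontal_Sup_L,-29.9,35.6,36.5,Frontal_L,Cerebrum_L
4,Frontal_Sup_R,23.7,38.1,41.9,Frontal_R,Cerebrum_R
5,Frontal_Sup_Orb_L,-35.9,34.8,19.4,Frontal_L,Cerebrum_L
6,Frontal_Sup_Orb_R,30.9,31,36.7,Frontal_R,Cerebrum_R
7,Frontal_Mid_L,-25.5,22.2,31.8,Frontal_L,Cerebrum_L
8,Frontal_Mid_R,34.7,40.5,34.7,Frontal_R,Cerebrum_R
9,Frontal_Mid_Orb_L,-47.3,43.8,20.1,Frontal_L,Cerebrum_L
10,Frontal_Mid_Orb_R,22.2,35,40.3,Frontal_R,Cerebrum_R
11,Frontal_Inf_Oper_L,-33.8,26.9,38.5,Frontal_L,Cerebrum_L
12,Frontal_Inf_Oper_R,37.5,44.8,33.1,Frontal_R,Cerebrum_R
13,Frontal_Inf_Tri_L,-29.9,41.8,28.5,Frontal_L,Cerebrum_L
14,Frontal_Inf_Tri_R,41.1,36.1,16.7,Frontal_R,Cerebrum_R
15,Frontal_Inf_Orb_L,-26.4,34.2,31.2,Frontal_L,Cerebrum_L
16,Frontal_Inf_Orb_R,47.4,34.5,27.4,Frontal_R,Cerebrum_R
17,Rolandic_Oper_L,-31,22.2,23.3,Frontal_L,Cerebrum_L
18,Rolandic_Oper_R,32.9,48.7,21.9,Frontal_R,Cerebrum_R
19,Supp_Motor_Area_L,-41.8,42.5,27.6,Frontal_L,Cerebrum_L
20,Supp_Motor_Area_R,37.5,21.6,25.8,Frontal_R,Cerebrum_R
21,Olfactory_L,-40,42.5,30.1,Frontal_L,Cerebrum_L
22,Olfactory_R,47.4,48.3,37.7,Frontal_R,Cerebrum_R
23,Frontal_Sup_Medial_L,-42.2,43.9,17.4,Frontal_L,Cerebrum_L
24,Frontal_Sup_Medial_R,46.5,33.9,34.7,Frontal_R,Cerebrum_R
25,Frontal_Med_Orb_L,-39.4,47.2,28.8,Frontal_L,Cerebrum_L
26,Frontal_Med_Orb_R,29.4,33.6,28,Frontal_R,Cerebrum_R
27,Rectus_L,-29.5,40.9,16.5,Frontal_L,Cerebrum_L
28,Rectus_R,48.6,48.2,43.3,Frontal_R,Cerebrum_R
29,Insula_L,-21.8,-11.1,16.8,Sub_lobar_L,Cerebrum_L
30,Insula_R,12,-13.7,-9,Sub_lobar_R,Cerebrum_R
31,Cingulum_Ant_L,-18.7,-15.7,4.2,Limbic_L,Cerebrum_L
32,Cingulum_Ant_R,11.1,-17.9,7.9,Limbic_R,Cerebrum_R
33,Cingulum_Mid_L,-21.5,-22.8,7.8,Limbic_L,Cerebrum_L
34,Cingulum_Mid_R,5,-17.4,16.7,Limbic_R,Cerebrum_R
35,Cingulum_Post_L,-5,-11.2,20.5,Limbic_L,Cerebrum_L
36,Cingulum_Post_R,25.8,-19.1,15.2,Limbic_R,Cerebrum_R
37,Hippocampus_L,-5,-19.9,12.6,Limbic_L,Cerebrum_L
38,Hippocampus_R,24.4,-12.4,5.9,Limbic_R,Cerebrum_R
39,ParaHippocampal_L,-13.8,-10.7,14.2,Limbic_L,Cerebrum_L
40,ParaHippocampal_R,13.6,-22.5,12.2,Limbic_R,Cerebrum_R
41,Amygdala_L,-24,-19.9,27.7,Limbic_L,Cerebrum_L
42,Amygdala_R,25.1,-24.2,10.9,Limbic_R,Cerebrum_R
43,Calcarine_L,-35.2,-91.6,4,Occipital_L,Cerebrum_L
44,Calcarine_R,30.2,-97.1,15.2,Occipital_R,Cerebrum_R
45,Cuneus_L,-33.1,-91.4,17.2,Occipital_L,Cerebrum_L
46,Cuneus_R,20,-95.4,13,Occipital_R,Cerebrum_R
47,Lingual_L,-17.2,-95.6,11,Occipital_L,Cerebrum_L
48,Lingual_R,34.5,-90.3,8.9,Occipital_R,Cerebrum_R
49,Occipital_Sup_L,-31.5,-85.1,12.4,Occipital_L,Cerebrum_L
50,Occipital_Sup_R,33.4,-90.6,11.8,Occipital_R,Cerebrum_R
51,Occipital_Mid_L,-31.5,-71.8,8.2,Occipital_L,Cerebrum_L
52,Occipital_Mid_R,11.6,-75.7,-8.8,Occipital_R,Cerebrum_R
53,Occipital_Inf_L,-37.6,-91.5,14.1,Occipital_L,Cerebrum_L
54,Occipital_Inf_R,19.7,-85.2,8,Occipital_R,Cerebrum_R
55,Fusiform_L,-48.3,-16,-14.4,Temporal_L,Cerebrum_L
56,Fusiform_R,62.7,-22.9,-20.8,Temporal_R,Cerebrum_R
57,Postcentral_L,-21.6,-68.7,51.3,Parietal_L,Cerebrum_L
58,Postcentral_R,44.7,-53.2,57.9,Parietal_R,Cerebrum_R
59,Parietal_Sup_L,-38.3,-67.4,33.7,Parietal_L,Cerebrum_L
60,Parietal_Sup_R,42.6,-53.5,43.6,Parietal_R,Cerebrum_R
61,Parietal_Inf_L,-26.7,-58.4,35.6,Parietal_L,Cerebrum_L
62,Parietal_Inf_R,46,-54.2,36.7,Parietal_R,Cerebrum_R
63,SupraMarginal_L,-26.6,-67.7,56.8,Parietal_L,Cerebrum_L
64,SupraMarginal_R,28.9,-44.8,46.4,Parietal_R,Cerebrum_R
65,Angular_L,-47.5,-67.4,33.9,Parietal_L,Cerebrum_L
66,Angular_R,27.3,-46.2,45.9,Parietal_R,Cerebrum_R
67,Precuneus_L,-44.6,-58.6,57.6,Parietal_L,Cerebrum_L
68,Precuneus_R,45.9,-57.5,36.1,Parietal_R,Cerebrum_R
69,Paracentral_Lobule_L,-32.2,-62.2,58.7,Parietal_L,Cerebrum_L
70,Paracentral_Lobule_R,45.4,-64.1,47.3,Parietal_R,Cerebrum_R
71,Caudate_L,-32.8,13.8,3.2,Sub_lobar_L,Cerebrum_L
72,Caudate_R,11.4,-9.4,16.6,Sub_lobar_R,Cerebrum_R
73,Putamen_L,-23.7,5.9,7.4,Sub_lobar_L,Cerebrum_L
74,Putamen_R,20.6,2.5,9.1,Sub_lobar_R,Cerebrum_R
75,Pallidum_L,-8,10.7,-5.3,Sub_lobar_L,Cerebrum_L
76,Pallidum_R,6.6,5.6,-8.8,Sub_lobar_R,Cerebrum_R
77,Thalamus_L,-11.4,0.4,9.8,Sub_lobar_L,Cerebrum_L
78,Thalamus_R,23.9,-3.4,-4.7,Sub_lobar_R,Cerebrum_R
79,Heschl_L,-42.6,-24.8,-20.2,Temporal_L,Cerebrum_L
80,Heschl_R,52.4,-25.6,-28,Temporal_R,Cerebrum_R
81,Temporal_Sup_L,-45.4,-18.2,-7.1,Temporal_L,Cerebrum_L
82,Temporal_Sup_R,42.5,-13.4,-9.7,Temporal_R,Cerebrum_R
83,Temporal_Pole_Sup_L,-47.6,-13.2,-7.8,Temporal_L,Cerebrum_L
84,Temporal_Pole_Sup_R,52.3,-9.6,-8.9,Temporal_R,Cerebrum_R
85,Temporal_Mid_L,-63.8,-12.3,-26.2,Temporal_L,Cerebrum_L
86,Temporal_Mid_R,56.5,-31.3,-19,Temporal_R,Cerebrum_R
87,Temporal_Pole_Mid_L,-56.1,-22.1,-22.8,Temporal_L,Cerebrum_L
88,Temporal_Pole_Mid_R,62.6,-6.2,-5.9,Temporal_R,Cerebrum_R
89,Temporal_Inf_L,-62.6,-24.4,-9,Temporal_L,Cerebrum_L
90,Temporal_Inf_R,48.5,-19,-4,Temporal_R,Cerebrum_R
91,Cerebelum_Crus1_L,-16.2,-74.9,-34.1,Cerebellum_Post_L,Cerebellum_L
92,Cerebelum_Crus1_R,21.8,-51.7,-27.2,Cerebellum_Post_R,Cerebellum_R
93,Cerebelum_Crus2_L,-23.7,-66.4,-39.7,Cerebellum_Post_L,Cerebellum_L
94,Cerebelum_Crus2_R,24.6,-60.7,-32.1,Cerebellum_Post_R,Cerebellum_R
95,Cerebelum_3_L,-20.7,-31.3,-20.5,Cerebellum_Ant_L,Cerebellum_L
96,Cerebelum_3_R,8.5,-34.8,-27,Cerebellum_Ant_R,Cerebellum_R
97,Cerebelum_4_5_L,-25.1,-35.8,-34.7,Cerebellum_Ant_L,Cerebellum_L
98,Cerebelum_4_5_R,12.8,-46.3,-21.6,Cerebellum_Ant_R,Cerebellum_R
99,Cerebelum_6_L,-36.3,-78.9,-35.1,Cerebellum_Post_L,Cerebellum_L
100,Cerebelum_6_R,27.3,-60.8,-46.2,Cerebellum_Post_R,Cerebellum_R
101,Cerebelum_7b_L,-21.7,-75.2,-32.2,Cerebellum_Post_L,Cerebellum_L
102,Cerebelum_7b_R,22.2,-58.2,-44.3,Cerebellum_Post_R,Cerebellum_R
103,Cerebelum_8_L,-30,-55.4,-39,Cerebellum_Post_L,Cerebellum_L
104,Cerebelum_8_R,25.7,-52,-51.7,Cerebellum_Post_R,Cerebellum_R
105,Cerebelum_9_L,-35.6,-72.3,-44.3,Cerebellum_Post_L,Cerebellum_L
106,Cerebelum_9_R,33.8,-52.1,-30.2,Cerebellum_Post_R,Cerebellum_R
107,Cerebelum_10_L,-13.7,-66.9,-47.2,Cerebellum_Post_L,Cerebellum_L
108,Cerebelum_10_R,24.9,-56.8,-37.9,Cerebellum_Post_R,Cerebellum_R
109,Vermis_1_2,0.2,-42.8,-22,Vermis_Ant,Midline
110,Vermis_3,-0.7,-46.5,-24.8,Vermis_Ant,Midline
111,Vermis_4_5,2,-60.7,-25.8,Vermis_Ant,Midline
112,Vermis_6,-1.8,-70.7,-28.8,Vermis_Post,Midline
113,Vermis_7,-2.3,-66.9,-32.8,Vermis_Post,Midline
114,Vermis_8,0.3,-65.4,-47,Vermis_Post,Midline
115,Vermis_9,-0.4,-54.4,-33.6,Vermis_Post,Midline
116,Vermis_10,1.9,-74,-30.1,Vermis_Post,Midline
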