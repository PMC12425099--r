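label	x	y	z	location_group
AAL_OccipitalLobe_1_L	-25	-92	2	OccipitalLobe
AAL_OccipitalLobe_1_R	25	-92	2	OccipitalLobe
AAL_OccipitalLobe_2_L	-28	-88	6	OccipitalLobe
AAL_OccipitalLobe_2_R	28	-88	6	OccipitalLobe
AAL_OccipitalLobe_3_L	-24	-89	5	OccipitalLobe
AAL_OccipitalLobe_3_R	24	-89	5	OccipitalLobe
AAL_OccipitalLobe_4_L	-21	-88	7	OccipitalLobe
AAL_OccipitalLobe_4_R	21	-88	7	OccipitalLobe
AAL_OccipitalLobe_5_L	-26	-86	6	OccipitalLobe
AAL_OccipitalLobe_5_R	26	-86	6	OccipitalLobe
AAL_OccipitalLobe_6_L	-16	-82	8	OccipitalLobe
AAL_OccipitalLobe_6_R	16	-82	8	OccipitalLobe
AAL_OccipitalLobe_7_L	-15	-87	11	OccipitalLobe
AAL_OccipitalLobe_7_R	15	-87	11	OccipitalLobe
AAL_OccipitalLobe_8_L	-25	-82	6	OccipitalLobe
AAL_OccipitalLobe_8_R	25	-82	6	OccipitalLobe
AAL_TemporalLobe_1_L	-64	-17	-3	TemporalLobe
AAL_TemporalLobe_1_R	64	-17	-3	TemporalLobe
AAL_TemporalLobe_2_L	-57	-23	-10	TemporalLobe
AAL_TemporalLobe_2_R	57	-23	-10	TemporalLobe
AAL_TemporalLobe_3_L	-58	-18	-10	TemporalLobe
AAL_TemporalLobe_3_R	58	-18	-10	TemporalLobe
AAL_TemporalLobe_4_L	-60	-24	-4	TemporalLobe
AAL_TemporalLobe_4_R	60	-24	-4	TemporalLobe
AAL_TemporalLobe_5_L	-59	-20	-12	TemporalLobe
AAL_TemporalLobe_5_R	59	-20	-12	TemporalLobe
AAL_TemporalLobe_6_L	-52	-16	-2	TemporalLobe
AAL_TemporalLobe_6_R	52	-16	-2	TemporalLobe
AAL_TemporalLobe_7_L	-62	-21	-14	TemporalLobe
AAL_TemporalLobe_7_R	62	-21	-14	TemporalLobe
AAL_TemporalLobe_8_L	-60	-14	-9	TemporalLobe
AAL_TemporalLobe_8_R	60	-14	-9	TemporalLobe
AAL_Cerebellum_1_L	-28	-62	-35	Cerebellum
AAL_Cerebellum_1_R	28	-62	-35	Cerebellum
AAL_Cerebellum_2_L	-21	-62	-31	Cerebellum
AAL_Cerebellum_2_R	21	-62	-31	Cerebellum
AAL_Cerebellum_3_L	-16	-70	-29	Cerebellum
AAL_Cerebellum_3_R	16	-70	-29	Cerebellum
AAL_Cerebellum_4_L	-15	-60	-30	Cerebellum
AAL_Cerebellum_4_R	15	-60	-30	Cerebellum
AAL_Cerebellum_5_L	-23	-60	-31	Cerebellum
AAL_Cerebellum_5_R	23	-60	-31	Cerebellum
AAL_Cerebellum_6_L	-30	-61	-31	Cerebellum
AAL_Cerebellum_6_R	30	-61	-31	Cerebellum
AAL_Cerebellum_7_L	-28	-58	-32	Cerebellum
AAL_Cerebellum_7_R	28	-58	-32	Cerebellum
AAL_Cerebellum_8_L	-25	-60	-33	Cerebellum
AAL_Cerebellum_8_R	25	-60	-33	Cerebellum
AAL_Cerebellum_9_L	-19	-61	-33	Cerebellum
AAL_Cerebellum_9_R	19	-61	-33	Cerebellum
AAL_BasalGanglia_1_L	-20	4	-8	BasalGanglia
AAL_BasalGanglia_1_R	20	4	-8	BasalGanglia
AAL_BasalGanglia_2_L	-25	10	3	BasalGanglia
AAL_BasalGanglia_2_R	25	10	3	BasalGanglia
AAL_BasalGanglia_3_L	-19	1	-1	BasalGanglia
AAL_BasalGanglia_3_R	19	1	-1	BasalGanglia
AAL_BasalGanglia_4_L	-27	-4	1	BasalGanglia
AAL_BasalGanglia_4_R	27	-4	1	BasalGanglia
AAL_CingulateGyrus_1_L	-8	-12	40	CingulateGyrus
AAL_CingulateGyrus_1_R	8	-12	40	CingulateGyrus
AAL_CingulateGyrus_2_L	-6	-13	31	CingulateGyrus
AAL_CingulateGyrus_2_R	6	-13	31	CingulateGyrus
AAL_CingulateGyrus_3_L	-3	-11	39	CingulateGyrus
AAL_CingulateGyrus_3_R	3	-11	39	CingulateGyrus
AAL_Insula_1_L	-33	7	-3	Insula
AAL_Insula_1_R	33	7	-3	Insula
AAL_Thalamus_1_L	-7	-19	13	Thalamus
AAL_Thalamus_1_R	7	-19	13	Thalamus
AAL_Hippocampus_1_L	-27	-24	-6	Hippocampus
AAL_Hippocampus_1_R	27	-24	-6	Hippocampus
AAL_Hippocampus_2_L	-27	-20	-19	Hippocampus
AAL_Hippocampus_2_R	27	-20	-19	Hippocampus
AAL_Amygdala_1_L	-30	-3	-18	Amygdala
AAL_Amygdala_1_R	30	-3	-18	Amygdala
AAL_PrecentralGyrus_1_L	-38	-7	43	PrecentralGyrus
AAL_PrecentralGyrus_1_R	38	-7	43	PrecentralGyrus
AAL_PostcentralGyrus_1_L	-36	-26	60	PostcentralGyrus
AAL_PostcentralGyrus_1_R	36	-26	60	PostcentralGyrus
AAL_SuperiorFrontalGyrus_1_L	-25	33	49	SuperiorFrontalGyrus
AAL_SuperiorFrontalGyrus_1_R	25	33	49	SuperiorFrontalGyrus
AAL_SuperiorFrontalGyrus_2_L	-23	30	45	SuperiorFrontalGyrus
AAL_SuperiorFrontalGyrus_2_R	23	30	45	SuperiorFrontalGyrus
AAL_SuperiorFrontalGyrus_3_L	-22	25	55	SuperiorFrontalGyrus
AAL_SuperiorFrontalGyrus_3_R	22	25	55	SuperiorFrontalGyrus
AAL_MiddleFrontalGyrus_1_L	-34	35	35	MiddleFrontalGyrus
AAL_MiddleFrontalGyrus_1_R	34	35	35	MiddleFrontalGyrus
AAL_MiddleFrontalGyrus_2_L	-39	35	40	MiddleFrontalGyrus
AAL_MiddleFrontalGyrus_2_R	39	35	40	MiddleFrontalGyrus
AAL_InferiorFrontalGyrus_1_L	-47	15	18	InferiorFrontalGyrus
AAL_InferiorFrontalGyrus_1_R	47	15	18	InferiorFrontalGyrus
AAL_InferiorFrontalGyrus_2_L	-45	21	19	InferiorFrontalGyrus
AAL_InferiorFrontalGyrus_2_R	45	21	19	InferiorFrontalGyrus
AAL_InferiorFrontalGyrus_3_L	-49	10	22	InferiorFrontalGyrus
AAL_InferiorFrontalGyrus_3_R	49	10	22	InferiorFrontalGyrus
AAL_OrbitofrontalCortex_1_L	-24	46	-18	OrbitofrontalCortex
AAL_OrbitofrontalCortex_1_R	24	46	-18	OrbitofrontalCortex
AAL_OrbitofrontalCortex_2_L	-29	48	-11	OrbitofrontalCortex
AAL_OrbitofrontalCortex_2_R	29	48	-11	OrbitofrontalCortex
AAL_OrbitofrontalCortex_3_L	-26	48	-9	OrbitofrontalCortex
AAL_OrbitofrontalCortex_3_R	26	48	-9	OrbitofrontalCortex
AAL_InferiorParietalLobe_1_L	-44	-45	45	InferiorParietalLobe
AAL_InferiorParietalLobe_1_R	44	-45	45	InferiorParietalLobe
AAL_InferiorParietalLobe_2_L	-41	-54	51	InferiorParietalLobe
AAL_InferiorParietalLobe_2_R	41	-54	51	InferiorParietalLobe
AAL_InferiorParietalLobe_3_L	-48	-37	43	InferiorParietalLobe
AAL_InferiorParietalLobe_3_R	48	-37	43	InferiorParietalLobe
AAL_InferiorParietalLobe_4_L	-50	-52	55	InferiorParietalLobe
AAL_InferiorParietalLobe_4_R	50	-52	55	InferiorParietalLobe
AAL_SuperiorParietalLobe_1_L	-28	-65	61	SuperiorParietalLobe
AAL_SuperiorParietalLobe_1_R	28	-65	61	SuperiorParietalLobe
AAL_SuperiorParietalLobe_2_L	-25	-57	64	SuperiorParietalLobe
AAL_SuperiorParietalLobe_2_R	25	-57	64	SuperiorParietalLobe
AAL_SuperiorParietalLobe_3_L	-25	-68	58	SuperiorParietalLobe
AAL_SuperiorParietalLobe_3_R	25	-68	58	SuperiorParietalLobe
AAL_Brainstem_1_L	-3	-32	-39	Brainstem
AAL_Brainstem_1_R	3	-32	-39	Brainstem
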