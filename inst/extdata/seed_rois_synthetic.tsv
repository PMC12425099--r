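label	x	y	z	location_group
Pain_Insula_1_L	-49	4	5	Insula
Pain_Insula_1_R	49	4	5	Insula
Pain_Insula_2_L	-41	12	4	Insula
Pain_Insula_2_R	41	12	4	Insula
Pain_Insula_3_L	-43	4	-3	Insula
Pain_Insula_3_R	43	4	-3	Insula
Pain_Insula_4_L	-40	8	0	Insula
Pain_Insula_4_R	40	8	0	Insula
Pain_Insula_5_L	-43	2	-2	Insula
Pain_Insula_5_R	43	2	-2	Insula
Pain_Insula_6_L	-38	2	6	Insula
Pain_Insula_6_R	38	2	6	Insula
Pain_Thalamus_1_L	-8	-19	8	Thalamus
Pain_Thalamus_1_R	8	-19	8	Thalamus
Pain_Thalamus_2_L	-8	-22	2	Thalamus
Pain_Thalamus_2_R	8	-22	2	Thalamus
Pain_Thalamus_3_L	-5	-17	15	Thalamus
Pain_Thalamus_3_R	5	-17	15	Thalamus
Pain_Thalamus_4_L	-12	-14	10	Thalamus
Pain_Thalamus_4_R	12	-14	10	Thalamus
Pain_Thalamus_5_L	-12	-27	15	Thalamus
Pain_Thalamus_5_R	12	-27	15	Thalamus
Pain_Amygdala_1_L	-21	-2	-20	Amygdala
Pain_Amygdala_1_R	21	-2	-20	Amygdala
Pain_Amygdala_2_L	-20	6	-13	Amygdala
Pain_Amygdala_2_R	20	6	-13	Amygdala
Pain_CingulateGyrus_1_L	-7	-6	34	CingulateGyrus
Pain_CingulateGyrus_1_R	7	-6	34	CingulateGyrus
Pain_CingulateGyrus_2_L	-9	-9	44	CingulateGyrus
Pain_CingulateGyrus_2_R	9	-9	44	CingulateGyrus
Pain_CingulateGyrus_3_L	-6	-12	37	CingulateGyrus
Pain_CingulateGyrus_3_R	6	-12	37	CingulateGyrus
Pain_CingulateGyrus_4_L	0	-9	34	CingulateGyrus
Pain_CingulateGyrus_4_R	0	-9	34	CingulateGyrus
Pain_OrbitofrontalCortex_1_L	-31	43	-15	OrbitofrontalCortex
Pain_OrbitofrontalCortex_1_R	31	43	-15	OrbitofrontalCortex
Pain_OrbitofrontalCortex_2_L	-28	42	-16	OrbitofrontalCortex
Pain_OrbitofrontalCortex_2_R	28	42	-16	OrbitofrontalCortex
Pain_OrbitofrontalCortex_3_L	-24	42	-7	OrbitofrontalCortex
Pain_OrbitofrontalCortex_3_R	24	42	-7	OrbitofrontalCortex
Pain_InferiorFrontalGyrus_1_L	-53	16	20	InferiorFrontalGyrus
Pain_InferiorFrontalGyrus_1_R	53	16	20	InferiorFrontalGyrus
Pain_InferiorFrontalGyrus_2_L	-52	11	11	InferiorFrontalGyrus
Pain_InferiorFrontalGyrus_2_R	52	11	11	InferiorFrontalGyrus
Pain_MiddleFrontalGyrus_1_L	-41	33	29	MiddleFrontalGyrus
Pain_MiddleFrontalGyrus_1_R	41	33	29	MiddleFrontalGyrus
Pain_SuperiorFrontalGyrus_1_L	-26	34	53	SuperiorFrontalGyrus
Pain_SuperiorFrontalGyrus_1_R	26	34	53	SuperiorFrontalGyrus
Pain_PrecentralGyrus_1_L	-39	-6	54	PrecentralGyrus
Pain_PrecentralGyrus_1_R	39	-6	54	PrecentralGyrus
Pain_PostcentralGyrus_1_L	-41	-20	49	PostcentralGyrus
Pain_PostcentralGyrus_1_R	41	-20	49	PostcentralGyrus
Pain_PostcentralGyrus_2_L	-44	-27	51	PostcentralGyrus
Pain_PostcentralGyrus_2_R	44	-27	51	PostcentralGyrus
Pain_InferiorParietalLobe_1_L	-42	-40	46	InferiorParietalLobe
Pain_InferiorParietalLobe_1_R	42	-40	46	InferiorParietalLobe
Pain_InferiorParietalLobe_2_L	-45	-44	44	InferiorParietalLobe
Pain_InferiorParietalLobe_2_R	45	-44	44	InferiorParietalLobe
Pain_InferiorParietalLobe_3_L	-51	-47	49	InferiorParietalLobe
Pain_InferiorParietalLobe_3_R	51	-47	49	InferiorParietalLobe
Pain_SuperiorParietalLobe_1_L	-22	-57	54	SuperiorParietalLobe
Pain_SuperiorParietalLobe_1_R	22	-57	54	SuperiorParietalLobe
Pain_OccipitalLobe_1_L	-18	-88	7	OccipitalLobe
Pain_OccipitalLobe_1_R	18	-88	7	OccipitalLobe
Pain_TemporalLobe_1_L	-57	-17	-11	TemporalLobe
Pain_TemporalLobe_1_R	57	-17	-11	TemporalLobe
Pain_TemporalLobe_2_L	-52	-19	-8	TemporalLobe
Pain_TemporalLobe_2_R	52	-19	-8	TemporalLobe
Pain_Hippocampus_1_L	-22	-30	-12	Hippocampus
Pain_Hippocampus_1_R	22	-30	-12	Hippocampus
Pain_Hippocampus_2_L	-32	-25	-15	Hippocampus
Pain_Hippocampus_2_R	32	-25	-15	Hippocampus
Pain_BasalGanglia_1_L	-23	3	6	BasalGanglia
Pain_BasalGanglia_1_R	23	3	6	BasalGanglia
Pain_Brainstem_1_L	-1	-28	-30	Brainstem
Pain_Brainstem_1_R	1	-28	-30	Brainstem
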