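sample_id	asv_001	asv_002	asv_003	asv_004	asv_005	asv_006	asv_007	asv_008	asv_009	asv_010	asv_011	asv_012	asv_013	asv_014	asv_015	asv_016	asv_017	asv_018	asv_019	asv_020	asv_021	asv_022	asv_023	asv_024	asv_025	asv_026	asv_027	asv_028	asv_029	asv_030	asv_031	asv_032	asv_033	asv_034	asv_035
S041_2019_0p2um	1478	154	23	269	74	0	392	612	26	230	165	626	264	978	0	344	917	269	1215	0	11	2	0	14	0	26	7	43	2	0	0	28	26	0	0
S042_2019_0p2um	717	473	303	118	580	0	403	382	230	698	1068	1530	2187	968	0	649	507	770	795	1	68	18	0	29	5	11	11	49	4	0	8	7	28	0	0
S043_2019_0p2um	284	369	18	6	28	0	130	424	39	91	389	437	879	526	0	658	392	336	390	8	5	3	0	4	336	15	23	8	57	0	78	37	15	0	0
S044_2019_0p2um	270	226	6	6	13	0	160	285	14	165	261	464	945	387	0	373	649	1050	279	121	55	77	0	2	989	19	27	36	2131	0	1192	67	39	0	0
S045_2019_0p2um	300	203	91	3	35	0	186	88	21	63	93	200	304	13	0	257	539	218	38	11	32	45	0	6	843	15	8	25	1005	0	477	61	256	0	0
S046_2019_0p2um	61	461	9	109	6	0	43	21	105	93	127	110	240	35	0	161	103	60	126	16	107	186	0	26	555	100	63	251	464	0	304	68	91	0	0
S047_2019_0p2um	43	23	8	161	1	0	10	35	4	12	32	217	96	43	0	49	56	30	9	219	135	66	0	4	15	68	30	111	24	0	3	161	121	0	0
S048_2019_0p2um	71	36	1	680	1	0	21	44	0	15	85	165	98	28	0	42	115	105	30	340	545	162	0	0	31	263	74	497	7	0	6	208	195	0	0
S049_2019_0p2um	49	16	3	63	0	0	8	18	1	10	10	23	36	34	0	25	34	32	15	612	486	148	0	1	6	209	34	423	2	0	0	67	61	0	0
S050_2019_0p2um	19	26	0	27	0	0	47	37	0	112	86	26	47	62	0	67	79	37	131	353	321	98	0	0	29	38	141	528	9	0	3	61	31	0	0
S051_2019_3p0um	767	127	11	27	9	0	57	156	12	141	850	694	345	1270	0	244	160	158	299	0	37	34	0	3	8	55	14	24	0	0	3	26	30	0	0
S052_2019_3p0um	507	70	15	24	24	0	43	46	48	135	238	247	162	568	0	61	37	338	157	1	49	6	0	9	4	4	5	26	4	0	6	1	30	0	0
S053_2019_3p0um	179	927	4	37	8	0	352	258	13	114	473	488	543	413	0	368	540	146	108	5	116	21	0	4	431	20	7	70	922	0	175	7	122	0	0
S054_2019_3p0um	42	15	32	9	32	0	43	6	48	9	58	87	30	11	0	34	53	15	37	0	11	5	0	17	596	6	6	36	1531	0	1463	20	38	0	0
S055_2019_3p0um	19	38	97	54	22	0	85	18	42	25	63	69	162	153	0	22	196	32	32	9	194	34	0	28	187	36	37	81	973	0	382	69	159	0	0
S056_2019_3p0um	29	107	10	35	15	0	41	8	23	50	7	101	81	30	0	19	70	71	36	10	470	200	0	11	224	556	100	232	145	0	188	338	424	0	0
S057_2019_3p0um	75	11	1	111	1	0	209	60	0	41	42	52	114	66	0	48	142	84	51	82	784	790	0	4	39	311	405	368	19	0	8	749	698	0	0
S058_2019_3p0um	30	25	148	18	71	0	9	39	62	16	44	48	11	27	0	12	24	4	12	424	311	201	0	102	5	332	86	269	0	0	0	287	168	0	0
S059_2019_3p0um	25	30	5	56	3	0	22	18	4	29	45	25	33	18	0	93	35	9	13	222	625	836	0	25	13	505	655	846	6	0	2	272	275	0	0
S060_2019_3p0um	27	6	21	67	3	0	23	10	25	39	33	30	37	17	0	9	17	5	14	478	529	208	0	17	8	181	358	495	2	0	3	365	23	0	0
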