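sample_id	asv_001	asv_002	asv_003	asv_004	asv_005	asv_006	asv_007	asv_008	asv_009	asv_010	asv_011	asv_012	asv_013	asv_014	asv_015	asv_016	asv_017	asv_018	asv_019	asv_020	asv_021	asv_022	asv_023	asv_024	asv_025	asv_026	asv_027	asv_028	asv_029	asv_030	asv_031	asv_032	asv_033	asv_034	asv_035
S001_2016_0p2um	61	11	6085	19	3320	55	137	152	12755	0	161	109	530	138	248	381	0	126	221	2	6	3	2	168	2	4	0	0	4	0	0	6	13	0	7
S002_2016_0p2um	465	481	881	24	858	243	332	589	966	0	601	811	851	495	208	346	0	182	1618	3	18	9	6	137	6	7	6	20	2	0	1	15	8	0	9
S003_2016_0p2um	1458	854	417	3	546	328	228	191	1377	0	815	382	1090	494	496	371	0	223	177	22	17	4	12	57	23	9	7	42	10	0	8	11	26	0	10
S004_2016_0p2um	106	324	784	48	60	90	132	92	186	0	223	515	295	104	57	100	0	167	92	3	39	11	17	13	71	6	6	6	209	0	48	13	34	0	15
S005_2016_0p2um	390	226	40	29	107	109	63	186	24	0	97	605	113	99	310	353	0	233	162	2	88	59	33	24	340	20	9	17	549	0	193	25	280	0	58
S006_2016_0p2um	155	47	141	2267	49	104	219	113	103	0	79	190	104	46	56	157	0	88	95	2	116	64	180	17	76	124	54	17	77	0	11	101	441	0	389
S007_2016_0p2um	233	20	111	6	50	142	49	52	74	0	31	72	360	96	62	23	0	119	77	20	403	158	188	24	22	224	124	342	10	0	9	327	154	0	244
S008_2016_0p2um	19	19	12	37	22	12	54	294	25	0	4	145	50	51	23	48	0	30	15	591	253	72	75	20	2	121	63	301	5	0	3	436	151	0	122
S009_2016_0p2um	27	3	1	2	5	13	7	14	2	0	5	19	27	50	9	15	0	8	24	339	143	30	96	5	7	121	99	90	12	0	2	144	24	0	94
S010_2016_0p2um	44	14	19	110	3	6	32	15	19	0	21	35	26	41	36	49	0	13	20	566	87	79	113	2	1	51	18	60	0	0	0	51	43	0	16
S011_2016_3p0um	262	21	61	133	54	47	134	297	39	0	256	212	238	574	203	159	0	104	169	44	6	4	7	69	9	7	9	11	3	0	7	35	15	0	9
S012_2016_3p0um	250	68	261	1	646	70	352	120	193	0	539	272	136	462	201	157	0	79	123	0	41	4	4	117	117	9	22	45	23	0	131	6	12	0	20
S013_2016_3p0um	11	75	1119	0	1128	17	50	13	1903	0	37	77	29	24	37	50	0	53	15	1	17	5	5	979	34	9	3	0	54	0	39	6	20	0	16
S014_2016_3p0um	220	285	51	605	89	78	488	58	49	0	57	265	120	218	117	361	0	149	85	5	96	26	18	33	79	167	79	121	240	0	96	28	93	0	121
S015_2016_3p0um	65	37	0	0	0	13	47	14	3	0	45	45	48	63	54	81	0	58	53	2	63	51	16	1	412	31	9	33	1293	0	539	55	112	0	62
S016_2016_3p0um	23	37	1	137	5	51	63	67	1	0	94	100	158	33	84	66	0	126	15	8	157	180	340	1	508	419	98	531	354	0	225	313	706	0	664
S017_2016_3p0um	41	25	17	24	16	27	24	20	41	0	56	35	61	24	23	51	0	43	17	11	195	202	251	43	136	195	740	232	219	0	89	441	491	0	452
S018_2016_3p0um	136	7	15	126	7	30	26	68	10	0	8	10	22	13	11	18	0	11	3	266	308	204	248	13	25	238	99	579	36	0	7	372	150	0	485
S019_2016_3p0um	59	8	27	12	21	3	17	13	27	0	38	23	52	39	19	5	0	14	24	1030	1871	378	413	30	9	160	108	565	4	0	2	375	85	0	456
S020_2016_3p0um	9	7	3	6	0	6	5	23	0	0	6	10	0	8	15	6	0	0	2	1141	262	199	128	1	12	105	67	67	26	0	2	128	21	0	31
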