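sample_id	asv_001	asv_002	asv_003	asv_004	asv_005	asv_006	asv_007	asv_008	asv_009	asv_010	asv_011	asv_012	asv_013	asv_014	asv_015	asv_016	asv_017	asv_018	asv_019	asv_020	asv_021	asv_022	asv_023	asv_024	asv_025	asv_026	asv_027	asv_028	asv_029	asv_030	asv_031	asv_032	asv_033	asv_034	asv_035
S021_2017_0p2um	2157	202	86	0	38	0	913	823	95	133	0	882	1497	2469	603	0	1139	623	3005	12	176	9	24	1	1	15	8	0	0	71	2	24	15	40	0
S022_2017_0p2um	116	136	98	24	187	0	130	115	179	148	0	302	735	648	147	0	201	146	351	2	24	2	10	7	0	7	9	0	2	44	0	7	40	15	0
S023_2017_0p2um	1396	244	1285	45	1139	0	266	86	1400	81	0	286	247	344	131	0	690	65	116	3	13	7	3	101	19	8	3	0	15	16	16	6	19	15	0
S024_2017_0p2um	261	152	12	3	15	0	57	34	2	97	0	482	313	172	815	0	204	80	166	3	65	5	16	1	15	23	6	0	162	36	8	9	31	31	0
S025_2017_0p2um	92	71	4	2442	17	0	44	26	5	30	0	118	77	73	84	0	844	78	151	3	58	37	40	1	82	22	24	0	64	58	31	51	83	20	0
S026_2017_0p2um	21	34	1	6756	2	0	8	19	1	3	0	21	24	27	5	0	54	8	14	4	17	12	47	1	7	23	5	0	6	54	2	142	47	19	0
S027_2017_0p2um	112	19	298	1788	175	0	54	42	297	34	0	128	193	91	15	0	119	8	77	13	321	69	307	66	13	187	58	0	5	1433	2	199	252	317	0
S028_2017_0p2um	34	24	8	8813	1	0	21	25	12	23	0	35	126	74	9	0	53	13	75	6	279	171	165	2	5	27	126	0	15	424	0	139	37	122	0
S029_2017_0p2um	28	51	2	26	3	0	45	7	8	25	0	68	126	20	69	0	49	17	28	125	911	209	779	0	7	43	95	0	8	116	3	304	30	177	0
S030_2017_0p2um	47	155	47	5	26	0	45	40	106	61	0	34	137	27	29	0	22	21	74	292	172	296	212	20	1	97	168	0	7	80	2	246	32	366	0
S031_2017_3p0um	223	25	402	5	621	0	191	182	455	209	0	55	75	222	225	0	71	102	117	2	14	14	7	294	2	24	23	0	1	28	0	6	5	11	0
S032_2017_3p0um	599	307	987	10	451	0	59	235	1703	576	0	217	269	598	115	0	337	188	231	11	29	36	23	338	3	59	4	0	2	80	1	11	32	13	0
S033_2017_3p0um	321	153	129	0	115	0	168	221	165	162	0	493	617	409	742	0	919	102	372	11	46	23	100	73	164	57	13	0	51	105	55	37	82	49	0
S034_2017_3p0um	46	245	16	244	6	0	102	118	14	24	0	920	192	35	81	0	235	51	75	16	55	17	48	16	191	29	21	0	407	81	190	57	105	31	0
S035_2017_3p0um	56	44	2	57	8	0	41	14	13	23	0	80	100	32	27	0	430	45	55	6	43	64	184	11	1413	30	7	0	978	876	1767	247	73	171	0
S036_2017_3p0um	23	13	0	2488	1	0	15	8	1	9	0	23	27	15	7	0	87	20	9	19	62	9	32	0	7	27	7	0	3	618	0	87	461	133	0
S037_2017_3p0um	24	15	5	749	7	0	7	17	16	8	0	10	24	27	5	0	108	6	16	3	206	39	265	23	279	160	174	0	144	607	27	89	394	278	0
S038_2017_3p0um	8	5	0	696	0	0	14	10	4	24	0	16	19	14	7	0	69	14	9	20	1037	163	204	1	7	792	529	0	8	420	5	409	241	272	0
S039_2017_3p0um	206	27	164	110	207	0	4	43	232	17	0	21	103	26	41	0	39	7	29	33	520	317	1391	224	87	467	973	0	41	255	39	964	268	197	0
S040_2017_3p0um	155	50	256	15	49	0	49	126	405	225	0	66	380	174	62	0	229	39	38	28	1884	1003	2732	121	177	2674	633	0	51	592	51	2073	255	1840	0
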