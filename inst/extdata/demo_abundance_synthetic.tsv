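taxon	S0001_T0	S0002_T0	S0003_T0	S0004_T0	S0005_T0	S0006_T0	S0007_T0	S0008_T0	S0009_T0	S0010_T0	S0011_T0	S0012_T0	S0001_T1	S0002_T1	S0003_T1	S0004_T1	S0005_T1	S0006_T1	S0007_T1	S0008_T1	S0009_T1	S0010_T1	S0011_T1	S0012_T1
p__Bacteroidetes;c__ClassA;o__OrderA;f__Bacteroidetesceae001;g__Genus001	0	111	844	297	1	0	165	540	1046	0	1104	0	0	81	639	252	1	1	154	372	259	0	567	2
p__Bacteroidetes;c__ClassA;o__OrderA;f__Bacteroidetesceae002;g__Genus002;s__species002	1	10	1153	760	0	2	669	104	1245	0	1176	0	0	10	851	741	0	2	587	56	312	0	661	292
p__Bacteroidetes;c__ClassA;o__OrderA;f__Bacteroidetesceae003;g__Genus003;s__species003	1	0	0	3	472	0	0	77	0	0	0	0	0	0	0	4	179	1	0	66	0	0	0	0
p__Bacteroidetes;c__ClassA;o__OrderA;f__Bacteroidetesceae004;g__Genus004;s__species004	75	0	0	0	3000	0	0	0	381	397	278	0	28	0	0	0	1214	25	0	0	110	401	184	7
p__Bacteroidetes;c__ClassA;o__OrderA;f__Bacteroidetesceae005;g__Genus005;s__species005	0	0	16	0	2274	0	9	0	0	0	0	4	82	1	16	0	913	11	20	0	1	0	78	9
p__Bacteroidetes;c__ClassA;o__OrderA;f__Bacteroidetesceae006;g__Genus006;s__species006	0	846	0	3	0	0	0	0	4	0	0	393	828	646	1	15	108	1	1	224	179	0	11	422
p__Bacteroidetes;c__ClassA;o__OrderA;f__Bacteroidetesceae007;g__Genus007;s__species007	262	0	0	6	3	335	0	0	12	289	26	0	103	466	123	1	1	341	23	1	2	330	121	0
p__Bacteroidetes;c__ClassA;o__OrderA;f__Bacteroidetesceae008;g__Genus008;s__species008	0	1	128	979	439	69	1779	583	1189	0	1410	298	0	6	105	843	171	68	1585	421	238	0	840	518
p__Bacteroidetes;c__ClassA;o__OrderA;f__Bacteroidetesceae009;g__Genus009;s__species009	208	0	141	83	0	0	765	25	335	0	168	0	79	0	113	73	0	0	683	16	88	0	86	54
p__Bacteroidetes;c__ClassA;o__OrderA;f__Bacteroidetesceae010;g__Genus010;s__species010	0	38	881	51	0	0	256	243	271	0	523	653	0	55	677	47	0	0	241	162	51	0	273	462
p__Bacteroidetes;c__ClassA;o__OrderA;f__Bacteroidetesceae011;g__Genus011	0	865	0	0	0	0	186	0	0	0	0	779	387	668	0	30	217	0	144	17	45	0	0	532
p__Bacteroidetes;c__ClassA;o__OrderA;f__Bacteroidetesceae012	8	0	74	73	2623	0	0	736	15	0	2	81	1	0	326	85	1063	8	21	519	7	0	5	50
p__Bacteroidetes;c__ClassA;o__OrderA;f__Bacteroidetesceae013;g__Genus013;s__species013	1036	0	0	0	2	269	0	0	0	171	3	0	327	155	328	0	1	243	14	0	0	156	187	0
p__Bacteroidetes;c__ClassA;o__OrderA;f__Bacteroidetesceae014;g__Genus014;s__species014	85	1932	0	0	29	0	0	0	54	0	0	1529	265	1397	1	50	771	1	2	176	1062	2	61	1076
p__Bacteroidetes;c__ClassA;o__OrderA;f__Bacteroidetesceae015;g__Genus015;s__species015	1126	1087	109	1	0	0	3	0	0	3	0	1689	537	772	75	23	255	0	2	14	49	3	47	1192
p__Bacteroidetes;c__ClassA;o__OrderA;f__Bacteroidetesceae016;g__Genus016;s__species016	0	0	0	108	198	8	0	0	2	0	49	28	0	0	0	85	82	22	0	0	1	0	19	23
p__Firmicutes;c__ClassA;o__OrderA;f__Firmicutesceae017;g__Genus017;s__species017	0	0	1336	55	7	0	281	175	903	0	331	0	0	0	1020	42	3	0	264	98	193	0	166	182
p__Firmicutes;c__ClassA;o__OrderA;f__Firmicutesceae018;g__Genus018;s__species018	0	2305	0	3	13	0	0	18	2	119	58	309	231	1724	6	22	722	0	0	80	657	123	35	225
p__Firmicutes;c__ClassA;o__OrderA;f__Firmicutesceae019;g__Genus019;s__species019	0	6	0	7	900	4	3	0	0	2	0	0	0	4	4	4	383	15	3	0	0	0	0	0
p__Firmicutes;c__ClassA;o__OrderA;f__Firmicutesceae020;g__Genus020;s__species020	147	3180	1112	121	452	883	105	41	195	321	71	3360	2918	2357	1093	412	4497	889	102	938	2281	290	104	2742
p__Firmicutes;c__ClassA;o__OrderA;f__Firmicutesceae021;g__Genus021;s__species021	379	0	0	0	0	130	0	5	4	98	0	0	120	80	158	0	0	143	29	9	0	96	173	1
p__Firmicutes;c__ClassA;o__OrderA;f__Firmicutesceae022;g__Genus022;s__species022	1284	47	545	0	17	2695	8	1	319	1054	122	0	385	1168	632	10	4	2645	147	0	88	1027	1098	0
p__Firmicutes;c__ClassA;o__OrderA;f__Firmicutesceae023;g__Genus023;s__species023	599	106	0	2219	2	1131	1	0	0	504	289	0	212	269	321	2114	2	1108	54	0	0	477	265	35
p__Firmicutes;c__ClassA;o__OrderA;f__Firmicutesceae024;g__Genus024;s__species024	59	0	0	0	2645	0	8	1	0	0	1	0	19	7	38	0	1179	57	8	38	1	0	0	25
p__Firmicutes;c__ClassA;o__OrderA;f__Firmicutesceae025;g__Genus025;s__species025	529	0	0	0	0	250	0	0	0	81	0	0	168	84	11	0	1	243	16	0	0	87	30	0
p__Firmicutes;c__ClassA;o__OrderA;f__Firmicutesceae026;g__Genus026;s__species026	0	0	364	416	0	0	150	382	173	0	25	0	0	1	294	388	0	0	133	247	34	0	30	120
p__Firmicutes;c__ClassA;o__OrderA;f__Firmicutesceae027;g__Genus027;s__species027	1	0	0	0	103	0	0	1	0	0	0	0	0	2	0	6	40	6	0	0	0	0	0	5
p__Firmicutes;c__ClassA;o__OrderA;f__Firmicutesceae028;g__Genus028;s__species028	611	0	0	0	0	884	0	0	0	372	9	0	241	283	139	0	1	866	122	0	109	348	560	0
p__Firmicutes;c__ClassA;o__OrderA;f__Firmicutesceae029;g__Genus029;s__species029	0	0	386	0	237	0	1	0	0	0	12	0	0	0	315	0	104	6	0	0	0	0	5	26
p__Firmicutes;c__ClassA;o__OrderA;f__Firmicutesceae030;g__Genus030;s__species030	47	469	1	1	22	34	5	0	42	1	5	57	218	326	0	63	1036	30	2	9	922	0	2	51
p__Firmicutes;c__ClassA;o__OrderA;f__Firmicutesceae031;g__Genus031;s__species031	0	1	1543	1233	22	0	183	455	554	0	982	42	13	0	1130	1168	9	0	170	282	117	0	549	227
p__Firmicutes;c__ClassA;o__OrderA;f__Firmicutesceae032;g__Genus032	3	0	4919	3693	784	270	4142	2039	1450	179	3732	96	56	116	3758	3500	305	265	3714	1425	678	191	2053	1802
p__Actinobacteria;c__ClassA;o__OrderA;f__Actinobacteriaceae033;g__Genus033;s__species033	0	0	0	5	474	0	0	0	0	0	1	0	0	0	33	1	238	7	0	0	3	0	103	0
p__Actinobacteria;c__ClassA;o__OrderA;f__Actinobacteriaceae034;g__Genus034;s__species034	1665	0	0	0	0	297	0	0	0	81	0	0	534	67	425	1	0	286	22	0	0	100	445	0
p__Actinobacteria;c__ClassA;o__OrderA;f__Actinobacteriaceae035;g__Genus035;s__species035	0	0	299	171	0	0	337	76	255	14	600	0	0	0	234	173	0	0	286	69	56	10	352	83
p__Actinobacteria;c__ClassA;o__OrderA;f__Actinobacteriaceae036	0	3	0	0	0	0	0	38	30	31	0	122	35	15	0	28	99	0	0	73	82	19	0	105
p__Actinobacteria;c__ClassA;o__OrderA;f__Actinobacteriaceae037;g__Genus037;s__species037	0	235	1	0	0	16	0	11	0	152	548	264	52	193	0	5	637	15	0	33	303	129	290	186
p__Actinobacteria;c__ClassA;o__OrderA;f__Actinobacteriaceae038;g__Genus038;s__species038	996	394	115	0	3	491	5	0	16	960	0	39	275	316	430	2	140	505	177	0	5	1023	748	25
p__Actinobacteria;c__ClassA;o__OrderA;f__Actinobacteriaceae039;g__Genus039	0	2061	3	9	6	0	2	78	0	0	0	2753	1510	1504	6	96	377	0	1	284	545	0	2	2047
p__Actinobacteria;c__ClassA;o__OrderA;f__Actinobacteriaceae040;g__Genus040;s__species040	777	0	27	6	42	698	605	0	0	2744	1	186	275	924	695	19	17	656	941	0	19	2761	1376	156
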