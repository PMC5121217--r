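otu_id	BR_d20	BR_d31	BR_d45	BR_d56	BR_d64	BR_d74	BR_d84
OTU_001	341	468	499	1315	1311	1663	1447
OTU_002	2988	2132	3425	2276	1709	1957	1816
OTU_003	1063	897	1056	1252	1171	1323	1642
OTU_004	827	1832	1289	847	1595	875	526
OTU_005	743	700	470	690	676	327	837
OTU_006	259	748	457	303	495	329	319
OTU_007	500	266	313	206	195	548	256
OTU_008	415	323	268	426	515	560	394
OTU_009	620	443	411	177	410	306	220
OTU_010	312	69	209	355	130	339	450
OTU_011	229	138	342	99	233	246	215
OTU_012	92	208	403	396	178	202	166
OTU_013	179	119	244	424	190	180	529
OTU_014	435	58	21	215	293	190	46
OTU_015	207	54	197	414	113	103	331
OTU_016	292	136	20	351	148	71	69
OTU_017	165	267	81	61	349	277	173
OTU_018	206	469	222	50	21	305	19
OTU_019	26	257	19	125	92	189	136
OTU_020	101	416	54	18	176	10	409
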