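locus	chromosome	allele	frequency	mini_only
INU055	CFA10	208	0.001	0
INU055	CFA10	210	0.176	0
INU055	CFA10	212	0.059	0
INU055	CFA10	214	0.342	0
INU055	CFA10	216	0.378	0
INU055	CFA10	218	0.028	0
INU055	CFA10	220	0.013	0
INU055	CFA10	222	0.002	1
AHT137	CFA11	131	0.238	0
AHT137	CFA11	133	0.008	0
AHT137	CFA11	135	0.001	0
AHT137	CFA11	137	0.172	0
AHT137	CFA11	141	0.349	0
AHT137	CFA11	143	0.017	0
AHT137	CFA11	145	0.038	0
AHT137	CFA11	147	0.067	0
AHT137	CFA11	149	0.008	0
AHT137	CFA11	151	0.102	0
AHTH130	CFA36	111	0.018	0
AHTH130	CFA36	117	0.002	0
AHTH130	CFA36	119	0.358	0
AHTH130	CFA36	121	0.14	0
AHTH130	CFA36	123	0.11	0
AHTH130	CFA36	127	0.117	0
AHTH130	CFA36	129	0.213	0
AHTH130	CFA36	131	0.02	0
AHTH130	CFA36	133	0.013	0
AHTH130	CFA36	135	0.009	1
AHTh171-A	CFA6	217	0.008	0
AHTh171-A	CFA6	219	0.362	0
AHTh171-A	CFA6	221	0.248	0
AHTh171-A	CFA6	223	0.008	0
AHTh171-A	CFA6	225	0.177	0
AHTh171-A	CFA6	227	0.009	0
AHTh171-A	CFA6	229	0.028	0
AHTh171-A	CFA6	231	0.003	0
AHTh171-A	CFA6	233	0.003	0
AHTh171-A	CFA6	235	0.135	0
AHTh171-A	CFA6	237	0.021	0
AHTh260	CFA16	238	0.571	0
AHTh260	CFA16	240	0.026	0
AHTh260	CFA16	242	0.001	1
AHTh260	CFA16	244	0.04	0
AHTh260	CFA16	246	0.22	0
AHTh260	CFA16	248	0.071	0
AHTh260	CFA16	250	0.021	0
AHTh260	CFA16	252	0.039	0
AHTh260	CFA16	254	0.004	0
AHTh260	CFA16	256	0.006	0
C22.279	CFA22	114	0.001	0
C22.279	CFA22	116	0.085	0
C22.279	CFA22	118	0.438	0
C22.279	CFA22	120	0.006	0
C22.279	CFA22	122	0.001	0
C22.279	CFA22	124	0.355	0
C22.279	CFA22	126	0.033	0
C22.279	CFA22	128	0.025	0
C22.279	CFA22	130	0.056	0
FH2054	CFA12	148	0.011	0
FH2054	CFA12	152	0.028	0
FH2054	CFA12	156	0.556	0
FH2054	CFA12	160	0.014	0
FH2054	CFA12	164	0.004	0
FH2054	CFA12	168	0.298	0
FH2054	CFA12	172	0.079	0
FH2054	CFA12	176	0.009	0
FH2054	CFA12	180	0.001	0
FH2848	CFA2	230	0.003	0
FH2848	CFA2	232	0.012	0
FH2848	CFA2	234	0.013	0
FH2848	CFA2	236	0.034	0
FH2848	CFA2	238	0.113	0
FH2848	CFA2	240	0.759	0
FH2848	CFA2	242	0.065	0
FH2848	CFA2	244	0.001	0
INRA21	CFA21	91	0.373	0
INRA21	CFA21	93	0.002	0
INRA21	CFA21	95	0.425	0
INRA21	CFA21	97	0.039	0
INRA21	CFA21	99	0.05	0
INRA21	CFA21	101	0.089	0
INRA21	CFA21	103	0.008	0
INRA21	CFA21	105	0.013	0
INRA21	CFA21	109	0.001	0
REN169D01	CFA14	202	0.008	0
REN169D01	CFA14	210	0.001	1
REN169D01	CFA14	212	0.06	0
REN169D01	CFA14	214	0.004	0
REN169D01	CFA14	216	0.394	0
REN169D01	CFA14	218	0.305	0
REN169D01	CFA14	220	0.001	0
REN169D01	CFA14	222	0.032	0
REN169D01	CFA14	224	0.18	0
REN169D01	CFA14	226	0.016	0
REN54P11	CFA18	222	0.003	0
REN54P11	CFA18	226	0.21	0
REN54P11	CFA18	228	0.205	0
REN54P11	CFA18	230	0.003	0
REN54P11	CFA18	232	0.353	0
REN54P11	CFA18	234	0.212	0
REN54P11	CFA18	236	0.006	0
REN54P11	CFA18	238	0.007	0
REN54P11	CFA18	242	0.001	0
AHTk211	CFA26	87	0.16	0
AHTk211	CFA26	89	0.042	0
AHTk211	CFA26	91	0.66	0
AHTk211	CFA26	93	0.002	1
AHTk211	CFA26	95	0.136	0
INU005	CFA33	110	0.022	0
INU005	CFA33	124	0.526	0
INU005	CFA33	126	0.431	0
INU005	CFA33	128	0.007	0
INU005	CFA33	130	0.009	0
INU005	CFA33	138	0.005	0
INU030	CFA12	144	0.316	0
INU030	CFA12	146	0.168	0
INU030	CFA12	148	0.064	0
INU030	CFA12	150	0.085	0
INU030	CFA12	152	0.365	0
INU030	CFA12	156	0.002	0
REN169O18	CFA29	156	0.001	0
REN169O18	CFA29	160	0.026	0
REN169O18	CFA29	162	0.594	0
REN169O18	CFA29	164	0.303	0
REN169O18	CFA29	166	0.01	0
REN169O18	CFA29	168	0.034	0
REN169O18	CFA29	170	0.026	0
REN169O18	CFA29	172	0.006	0
LEI004	CFA37	85	0.707	0
LEI004	CFA37	95	0.094	0
LEI004	CFA37	107	0.17	0
LEI004	CFA37	109	0.029	0
REN105L03	CFA11	227	0.014	0
REN105L03	CFA11	231	0.24	0
REN105L03	CFA11	233	0.175	0
REN105L03	CFA11	235	0.003	0
REN105L03	CFA11	237	0.014	0
REN105L03	CFA11	239	0.012	0
REN105L03	CFA11	241	0.542	0
REN105L03	CFA11	243	0.001	0
REN162C04	CFA2	200	0.021	0
REN162C04	CFA2	202	0.173	0
REN162C04	CFA2	204	0.057	0
REN162C04	CFA2	206	0.569	0
REN162C04	CFA2	208	0.082	0
REN162C04	CFA2	210	0.063	0
REN162C04	CFA2	212	0.035	0
AHTk253	CFA23	280	0.016	0
AHTk253	CFA23	284	0.157	0
AHTk253	CFA23	286	0.085	0
AHTk253	CFA23	288	0.399	0
AHTk253	CFA23	290	0.225	0
AHTk253	CFA23	292	0.119	0
FH2001	CFA23	124	0.007	0
FH2001	CFA23	132	0.443	0
FH2001	CFA23	136	0.043	0
FH2001	CFA23	140	0.019	0
FH2001	CFA23	144	0.273	0
FH2001	CFA23	148	0.207	0
FH2001	CFA23	152	0.008	0
REN247M23	CFA15	266	0.041	0
REN247M23	CFA15	268	0.481	0
REN247M23	CFA15	270	0.265	0
REN247M23	CFA15	272	0.209	0
REN247M23	CFA15	278	0.004	0
REN64E19	CFA34	139	0.001	0
REN64E19	CFA34	143	0.01	0
REN64E19	CFA34	145	0.432	0
REN64E19	CFA34	147	0.27	0
REN64E19	CFA34	149	0.032	0
REN64E19	CFA34	153	0.244	0
REN64E19	CFA34	155	0.01	0
AHT121	CFA13	92	0.019	0
AHT121	CFA13	94	0.028	0
AHT121	CFA13	96	0.011	0
AHT121	CFA13	98	0.341	0
AHT121	CFA13	100	0.092	0
AHT121	CFA13	102	0.004	0
AHT121	CFA13	104	0.161	0
AHT121	CFA13	106	0.076	0
AHT121	CFA13	108	0.203	0
AHT121	CFA13	110	0.044	0
AHT121	CFA13	112	0.019	0
AHT121	CFA13	114	0.001	0
VGL0760	CFA7	120	0.324	0
VGL0760	CFA7	130	0.001	0
VGL0760	CFA7	140	0.013	0
VGL0760	CFA7	150	0.018	0
VGL0760	CFA7	190	0.088	0
VGL0760	CFA7	192	0.132	0
VGL0760	CFA7	200	0.022	0
VGL0760	CFA7	202	0.18	0
VGL0760	CFA7	212	0.05	0
VGL0760	CFA7	222	0.013	0
VGL0760	CFA7	232	0.086	0
VGL0760	CFA7	242	0.061	0
VGL0760	CFA7	252	0.01	0
VGL0760	CFA7	262	0.001	1
VGL0910	CFA9	120	0.001	0
VGL0910	CFA9	130	0.046	0
VGL0910	CFA9	140	0.004	0
VGL0910	CFA9	150	0.006	0
VGL0910	CFA9	151	0.004	0
VGL0910	CFA9	161	0.003	0
VGL0910	CFA9	171	0.128	0
VGL0910	CFA9	181	0.289	0
VGL0910	CFA9	190	0.001	0
VGL0910	CFA9	191	0.147	0
VGL0910	CFA9	201	0.026	0
VGL0910	CFA9	211	0.278	0
VGL0910	CFA9	221	0.019	0
VGL0910	CFA9	230	0.038	0
VGL0910	CFA9	231	0.006	0
VGL0910	CFA9	240	0.001	0
VGL1063	CFA10	8	0.007	0
VGL1063	CFA10	9	0.004	1
VGL1063	CFA10	10	0.001	0
VGL1063	CFA10	11	0.003	0
VGL1063	CFA10	12	0.019	0
VGL1063	CFA10	13	0.181	0
VGL1063	CFA10	14	0.13	0
VGL1063	CFA10	15	0.051	0
VGL1063	CFA10	16	0.116	0
VGL1063	CFA10	17	0.029	0
VGL1063	CFA10	18	0.047	0
VGL1063	CFA10	19	0.359	0
VGL1063	CFA10	20	0.024	0
VGL1063	CFA10	21	0.017	0
VGL1063	CFA10	22	0.004	0
VGL1063	CFA10	23	0.006	0
VGL1063	CFA10	24	0.001	0
VGL1165	CFA11	14	0.001	1
VGL1165	CFA11	15	0.002	0
VGL1165	CFA11	16	0.049	0
VGL1165	CFA11	17	0.001	0
VGL1165	CFA11	18	0.016	0
VGL1165	CFA11	19	0.008	1
VGL1165	CFA11	20	0.001	0
VGL1165	CFA11	21	0.078	0
VGL1165	CFA11	22	0.002	0
VGL1165	CFA11	23	0.003	0
VGL1165	CFA11	24	0.021	0
VGL1165	CFA11	25	0.096	0
VGL1165	CFA11	26	0.469	0
VGL1165	CFA11	27	0.128	0
VGL1165	CFA11	28	0.117	0
VGL1165	CFA11	29	0.004	0
VGL1165	CFA11	30	0.003	1
VGL1165	CFA11	31	0.001	1
VGL1165	CFA11	32	0.001	1
VGL1165	CFA11	34	0.001	1
VGL1828	CFA18	15	0.001	0
VGL1828	CFA18	16	0.061	0
VGL1828	CFA18	17	0.022	0
VGL1828	CFA18	18	0.093	0
VGL1828	CFA18	19	0.478	0
VGL1828	CFA18	20	0.269	0
VGL1828	CFA18	21	0.047	0
VGL1828	CFA18	22	0.008	0
VGL2009	CFA20	9	0.388	0
VGL2009	CFA20	10	0.002	0
VGL2009	CFA20	11	0.058	0
VGL2009	CFA20	12	0.03	0
VGL2009	CFA20	13	0.245	0
VGL2009	CFA20	14	0.236	0
VGL2009	CFA20	15	0.042	0
VGL2409	CFA24	13	0.028	0
VGL2409	CFA24	14	0.254	0
VGL2409	CFA24	15	0.235	0
VGL2409	CFA24	16	0.127	0
VGL2409	CFA24	17	0.181	0
VGL2409	CFA24	18	0.13	0
VGL2409	CFA24	19	0.043	0
VGL2409	CFA24	20	0.001	1
VGL2918	CFA29	120	0.001	0
VGL2918	CFA29	130	0.099	0
VGL2918	CFA29	140	0.202	0
VGL2918	CFA29	150	0.17	0
VGL2918	CFA29	160	0.038	0
VGL2918	CFA29	163	0.001	0
VGL2918	CFA29	170	0.004	0
VGL2918	CFA29	173	0.043	0
VGL2918	CFA29	183	0.02	0
VGL2918	CFA29	193	0.11	0
VGL2918	CFA29	203	0.102	0
VGL2918	CFA29	213	0.154	0
VGL2918	CFA29	223	0.051	0
VGL2918	CFA29	233	0.004	0
VGL3008	CFA30	120	0.001	0
VGL3008	CFA30	130	0.01	0
VGL3008	CFA30	140	0.038	0
VGL3008	CFA30	150	0.22	0
VGL3008	CFA30	160	0.03	0
VGL3008	CFA30	170	0.562	0
VGL3008	CFA30	180	0.021	0
VGL3008	CFA30	182	0.001	0
VGL3008	CFA30	190	0.1	0
VGL3008	CFA30	200	0.015	0
VGL3008	CFA30	210	0.003	0
VGL3235	CFA32	12	0.15	0
VGL3235	CFA32	13	0.05	0
VGL3235	CFA32	14	0.14	0
VGL3235	CFA32	15	0.026	0
VGL3235	CFA32	16	0.336	0
VGL3235	CFA32	17	0.222	0
VGL3235	CFA32	18	0.074	0
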