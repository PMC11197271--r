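node	network
n001	DMN
n002	DMN
n003	DMN
n004	DMN
n005	DMN
n006	DMN
n007	DMN
n008	DMN
n009	DMN
n010	DMN
n011	DMN
n012	DMN
n013	DMN
n014	DMN
n015	DMN
n016	DMN
n017	DMN
n018	DMN
n019	DMN
n020	DMN
n021	DMN
n022	DMN
n023	DMN
n024	DMN
n025	DMN
n026	DMN
n027	DMN
n028	DMN
n029	DMN
n030	DMN
n031	DMN
n032	DMN
n033	DMN
n034	DMN
n035	DMN
n036	DMN
n037	DMN
n038	DMN
n039	DMN
n040	DMN
n041	DMN
n042	DMN
n043	DMN
n044	DMN
n045	DMN
n046	DMN
n047	DMN
n048	DMN
n049	DMN
n050	DMN
n051	DMN
n052	DMN
n053	DMN
n054	DMN
n055	DMN
n056	DMN
n057	DMN
n058	DMN
n059	DMN
n060	DMN
n061	DMN
n062	DMN
n063	DMN
n064	DMN
n065	DMN
n066	DMN
n067	DMN
n068	DMN
n069	DMN
n070	DMN
n071	DMN
n072	DMN
n073	DMN
n074	DMN
n075	DMN
n076	CE
n077	CE
n078	CE
n079	CE
n080	CE
n081	CE
n082	CE
n083	CE
n084	CE
n085	CE
n086	CE
n087	CE
n088	CE
n089	CE
n090	CE
n091	CE
n092	CE
n093	CE
n094	CE
n095	CE
n096	CE
n097	CE
n098	CE
n099	CE
n100	CE
n101	CE
n102	CE
n103	CE
n104	CE
n105	CE
n106	CE
n107	CE
n108	CE
n109	CE
n110	CE
n111	CE
n112	CE
n113	CE
n114	CE
n115	CE
n116	CE
n117	CE
n118	CE
n119	CE
n120	CE
n121	CE
n122	CE
n123	CE
n124	CE
n125	CE
n126	CE
n127	CE
n128	CE
n129	CE
n130	CE
n131	CE
n132	CE
n133	DS
n134	DS
n135	DS
n136	DS
n137	DS
n138	DS
n139	DS
n140	DS
n141	DS
n142	DS
n143	DS
n144	DS
n145	DS
n146	DS
n147	DS
n148	DS
n149	DS
n150	DS
n151	DS
n152	DS
n153	DS
n154	DS
n155	DS
n156	DS
n157	DS
n158	DS
n159	DS
n160	DS
n161	DS
n162	DS
n163	DS
n164	DS
n165	DS
n166	DS
n167	DS
n168	DS
n169	DS
n170	DS
n171	DS
n172	DS
n173	DS
n174	DS
n175	DS
n176	DS
n177	DS
n178	DS
n179	DS
n180	DS
n181	DS
n182	DS
n183	DS
n184	DS
n185	DS
n186	DS
n187	DS
n188	DS
n189	DS
n190	VS
n191	VS
n192	VS
n193	VS
n194	VS
n195	VS
n196	VS
n197	VS
n198	VS
n199	VS
n200	VS
n201	VS
n202	VS
n203	VS
n204	VS
n205	VS
n206	VS
n207	VS
n208	VS
n209	VS
n210	VS
n211	VS
n212	VS
n213	VS
n214	VS
n215	VS
n216	VS
n217	VS
n218	VS
n219	VS
n220	VS
n221	VS
n222	VS
n223	VS
n224	VS
n225	VS
n226	VS
n227	VS
n228	VS
n229	VS
n230	VS
n231	VS
n232	VS
n233	VS
n234	VS
n235	VS
n236	VS
n237	VS
n238	VS
n239	VS
n240	VS
n241	VS
n242	VS
n243	VS
n244	VS
n245	VS
n246	VS
n247	SM
n248	SM
n249	SM
n250	SM
n251	SM
n252	SM
n253	SM
n254	SM
n255	SM
n256	SM
n257	SM
n258	SM
n259	SM
n260	SM
n261	SM
n262	SM
n263	SM
n264	SM
n265	SM
n266	SM
n267	SM
n268	SM
n269	SM
n270	SM
n271	SM
n272	SM
n273	SM
n274	SM
n275	SM
n276	SM
n277	SM
n278	SM
n279	SM
n280	SM
n281	SM
n282	SM
n283	SM
n284	SM
n285	SM
n286	SM
n287	SM
n288	SM
n289	SM
n290	SM
n291	SM
n292	SM
n293	SM
n294	SM
n295	SM
n296	SM
n297	SM
n298	SM
n299	SM
n300	SM
n301	SM
n302	SM
n303	SM
n304	VI
n305	VI
n306	VI
n307	VI
n308	VI
n309	VI
n310	VI
n311	VI
n312	VI
n313	VI
n314	VI
n315	VI
n316	VI
n317	VI
n318	VI
n319	VI
n320	VI
n321	VI
n322	VI
n323	VI
n324	VI
n325	VI
n326	VI
n327	VI
n328	VI
n329	VI
n330	VI
n331	VI
n332	VI
n333	VI
n334	VI
n335	VI
n336	VI
n337	VI
n338	VI
n339	VI
n340	VI
n341	VI
n342	VI
n343	VI
n344	VI
n345	VI
n346	VI
n347	VI
n348	VI
n349	VI
n350	VI
n351	VI
n352	VI
n353	VI
n354	VI
n355	VI
n356	VI
n357	VI
n358	VI
n359	VI
n360	VI
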