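param	weight
W001	7.61911525e-01
W002	-2.27400391e-03
W003	2.47933323e-03
W004	-4.16648093e-03
W005	6.37081220e-03
W006	8.80819056e-03
W007	-7.00123390e-03
W008	-1.14063488e-04
W009	6.40453804e-01
W010	1.28662276e-02
W011	5.34914582e-03
W012	7.89436088e-03
W013	-2.14009700e-02
W014	-1.15438494e-02
W015	8.54256919e-03
W016	4.22469329e-03
W017	2.77986702e-03
W018	-1.51879158e-05
W019	-2.11380341e-05
W020	1.99641549e-04
W021	-1.29856368e-04
W022	-4.03673336e-05
W023	6.59754790e-05
W024	2.18857592e-04
W025	2.26216410e-03
W026	1.86027193e-04
W027	-1.58495161e-04
W028	-1.02118723e-04
W029	-2.77245753e-05
W030	1.93643502e-04
W031	-1.74700880e-04
W032	1.78743008e-06
W033	2.82332200e-03
W034	-9.86063090e-05
W035	2.25064114e-05
W036	1.23637997e-04
W037	8.76001690e-05
W038	-1.16497023e-04
W039	1.71698034e-04
W040	-3.34944763e-05
W041	1.69159191e-03
W042	-2.25649188e-04
W043	-2.50160443e-04
W044	-7.19354188e-05
W045	-1.47451933e-04
W046	2.51932384e-04
W047	-3.03102553e-04
W048	-4.41985547e-05
W049	-4.34859277e-03
W050	7.31280665e-05
W051	1.70716651e-04
W052	4.63931076e-05
W053	-3.44613448e-04
W054	-1.30174999e-04
W055	4.65463708e-05
W056	-3.05423085e-04
W057	-3.51554191e-03
W058	2.44556693e-05
W059	3.19044804e-04
W060	-2.04583376e-04
W061	9.96032037e-05
W062	3.47349172e-04
W063	7.01737910e-05
W064	1.59369217e-04
W065	4.27430775e-03
W066	8.88865797e-05
W067	-2.94056138e-04
W068	1.33975829e-04
W069	1.94178178e-04
W070	2.16198087e-04
W071	2.21837808e-04
W072	-8.10283474e-05
W073	3.20742796e-03
W074	1.25145678e-04
W075	4.28310658e-04
W076	-5.10924362e-05
W077	-2.85445769e-04
W078	-2.45223542e-04
W079	-1.87965569e-04
W080	-5.70489356e-05
W081	-3.52535515e-03
W082	-2.26728381e-04
W083	-1.90362852e-04
W084	2.08486548e-04
W085	7.76542340e-05
W086	-5.13674627e-05
W087	3.53208027e-04
W088	-3.15254601e-04
W089	-2.96634677e-03
W090	3.79759895e-04
W091	2.80417231e-04
W092	-1.17708115e-04
W093	-1.67293454e-04
W094	9.65021091e-05
W095	-2.93316930e-04
W096	3.86654765e-04
W097	-4.25609334e-03
W098	3.66645738e-05
W099	-9.21394363e-05
W100	-1.16567431e-04
W101	-1.28453959e-05
W102	6.72249504e-05
W103	-2.42556376e-04
W104	1.06080444e-04
W105	-3.17145041e-03
W106	-1.35632551e-04
W107	1.12336818e-04
W108	1.10241669e-04
W109	8.55182494e-05
W110	-1.22387515e-04
W111	2.76823655e-04
W112	-1.50491379e-05
W113	5.16705726e-03
W114	4.25765905e-04
W115	-2.62298949e-04
W116	-1.60141196e-04
W117	-6.60880716e-05
W118	-3.02352981e-04
W119	-6.72100536e-05
W120	1.41379179e-04
W121	3.85141914e-03
W122	-6.21606630e-05
W123	9.41872577e-05
W124	4.79203657e-05
W125	1.82395134e-04
W126	1.67673866e-04
W127	5.36471493e-05
W128	-1.90309606e-04
W129	-3.51073091e-02
W130	-1.51838118e-03
W131	1.01757674e-03
W132	-2.73211436e-03
W133	7.33560786e-03
W134	9.19692125e-03
W135	-8.05739865e-03
W136	6.51493423e-04
W137	-8.08571658e-03
W138	1.29060461e-02
W139	6.81473045e-03
W140	7.48357986e-03
W141	-2.24780233e-02
W142	-1.19099831e-02
W143	9.22031517e-03
W144	3.44669861e-03
W145	-1.90527709e-03
W146	-2.01367956e-05
W147	2.49282223e-05
W148	3.26764846e-04
W149	1.00601410e-04
W150	-1.56992942e-05
W151	-8.00413885e-05
W152	2.49408330e-04
W153	-2.15723299e-03
W154	-4.64298801e-05
W155	-9.53178680e-05
W156	-1.12884611e-04
W157	-9.12510086e-05
W158	-6.89488352e-05
W159	3.41499639e-05
W160	7.73001213e-05
W161	4.44210327e-04
W162	4.47580750e-05
W163	1.30576445e-05
W164	-4.90979976e-05
W165	-3.49219468e-05
W166	-8.19586855e-05
W167	1.08269164e-04
W168	-1.95622559e-04
W169	7.46780725e-04
W170	9.11476831e-05
W171	7.16739510e-05
W172	-1.57694769e-04
W173	-4.53230820e-05
W174	2.71574053e-04
W175	-1.67225147e-04
W176	1.43803657e-04
W177	1.09218585e-03
W178	1.79719867e-04
W179	1.61653390e-04
W180	-2.56582763e-04
W181	-1.32747407e-05
W182	-3.01070331e-05
W183	-3.20520875e-05
W184	6.34642751e-05
W185	6.56368968e-04
W186	-3.53591002e-04
W187	3.82636843e-04
W188	1.01094733e-04
W189	1.42142991e-04
W190	-4.04238891e-05
W191	2.80323512e-04
W192	-4.31170073e-05
W193	-6.00151619e-04
W194	-9.47126081e-05
W195	1.15150006e-04
W196	1.46935719e-04
W197	6.72766714e-05
W198	-1.19547775e-04
W199	1.57001427e-04
W200	-1.49824610e-04
W201	-4.91552298e-04
W202	8.95043482e-05
W203	1.63556349e-04
W204	4.71082557e-05
W205	-9.06935947e-05
W206	2.84414961e-05
W207	-1.17736335e-04
W208	2.20729201e-05
W209	4.72240078e-03
W210	1.86838122e-04
W211	-5.45137189e-05
W212	1.09541997e-04
W213	-1.59553754e-05
W214	-1.46712077e-04
W215	2.08417768e-04
W216	-2.05019129e-04
W217	3.80486149e-03
W218	-8.60849122e-05
W219	-1.08760911e-04
W220	-2.00683166e-04
W221	-9.95505013e-05
W222	4.34573582e-06
W223	-6.57565695e-05
W224	2.29690199e-04
W225	3.09131179e-03
W226	-1.77974959e-05
W227	4.79477000e-05
W228	-2.33955391e-04
W229	-8.92880531e-05
W230	3.85533002e-05
W231	2.19965118e-05
W232	1.97716550e-04
W233	2.25462737e-03
W234	-1.15065302e-04
W235	-1.06331017e-04
W236	1.88120997e-04
W237	3.75652909e-05
W238	4.79447744e-06
W239	6.53864104e-05
W240	4.52056904e-05
W241	1.23061499e-03
W242	2.28062409e-05
W243	-6.93806809e-05
W244	8.00763063e-05
W245	9.75483357e-05
W246	-1.56582122e-04
W247	-1.09362393e-04
W248	-1.15687416e-04
W249	1.24509748e-03
W250	-1.37155775e-04
W251	9.94987457e-06
W252	-9.78956539e-05
W253	-2.28930106e-04
W254	2.32967310e-04
W255	1.62689142e-04
W256	2.17381682e-04
W257	-6.12297045e-03
W258	-3.01011833e-03
W259	2.08710475e-03
W260	-5.27583717e-03
W261	1.32878929e-02
W262	1.70340214e-02
W263	-1.44288840e-02
W264	1.39917931e-03
W265	3.36884212e-02
W266	2.34660925e-02
W267	1.23788402e-02
W268	1.36523827e-02
W269	-4.11319813e-02
W270	-2.21228259e-02
W271	1.70802847e-02
W272	6.79432787e-03
W273	-1.60513494e-03
W274	1.13713216e-04
W275	9.22927162e-05
W276	4.27600061e-04
W277	6.40799213e-05
W278	1.15505720e-04
W279	-7.12189976e-05
W280	7.98497002e-05
W281	-1.62409020e-03
W282	-2.75827221e-04
W283	-1.02885379e-04
W284	-1.51777054e-04
W285	-5.41883877e-05
W286	-1.85298562e-04
W287	3.95105378e-06
W288	-4.65071273e-05
W289	-5.50415273e-03
W290	9.64670529e-05
W291	3.37348633e-04
W292	-6.22045792e-05
W293	7.23532200e-05
W294	1.85224601e-04
W295	2.75807665e-05
W296	-3.04383760e-04
W297	-3.66576947e-03
W298	-7.51843990e-05
W299	-2.42834897e-04
W300	1.27677492e-05
W301	-9.57108915e-05
W302	1.09455859e-04
W303	-3.35178394e-04
W304	1.18076153e-04
W305	2.66740957e-03
W306	1.59883632e-04
W307	1.13554719e-04
W308	1.17565767e-04
W309	-2.70390047e-05
W310	-6.41850967e-05
W311	8.64848088e-05
W312	1.46069997e-04
W313	1.97431852e-03
W314	3.31364237e-05
W315	2.69257907e-04
W316	-1.73922118e-04
W317	-1.49633791e-04
W318	1.29095625e-04
W319	-1.29500662e-04
W320	-1.78768930e-04
W321	8.20166105e-05
W322	-1.13134215e-05
W323	4.63917962e-06
W324	1.65071421e-04
W325	2.51727320e-04
W326	4.17470067e-05
W327	-2.85316373e-06
W328	-4.33529002e-04
W329	2.35597372e-04
W330	-4.84313205e-05
W331	2.17365099e-04
W332	-5.48833097e-06
W333	-1.46679488e-04
W334	1.97775863e-04
W335	-1.40882115e-04
W336	8.34082489e-05
W337	-2.03906235e-04
W338	-3.33711842e-05
W339	4.38532191e-05
W340	1.22599936e-04
W341	1.27770234e-04
W342	-2.18525382e-04
W343	2.25939971e-04
W344	-1.22984995e-04
W345	-4.80562346e-04
W346	1.53762336e-04
W347	-6.61627074e-05
W348	-5.44568945e-05
W349	-1.47268255e-04
W350	7.25597965e-05
W351	-1.02327952e-04
W352	1.82593582e-04
W353	-2.09097172e-05
W354	5.70715013e-05
W355	1.24143575e-04
W356	-5.77318516e-05
W357	1.78334452e-04
W358	2.03676341e-04
W359	2.65633100e-05
W360	2.31533531e-04
W361	7.75712292e-05
W362	1.08703278e-04
W363	-1.72451311e-05
W364	2.22364730e-04
W365	-1.10785513e-04
W366	-1.62293228e-04
W367	8.65643339e-05
W368	-1.25765945e-04
W369	5.12988770e-03
W370	2.68785128e-04
W371	-1.00685588e-04
W372	1.65375737e-04
W373	-2.45028579e-04
W374	-2.62009192e-04
W375	2.55750656e-04
W376	-4.02712629e-05
W377	3.89173045e-03
W378	-3.91371792e-04
W379	-8.78012974e-05
W380	-1.30775738e-04
W381	7.65312773e-05
W382	-7.38704884e-05
W383	-6.63952807e-05
W384	1.73943749e-04
logit_a	-3.79485036e+01
logit_b	1.56051865e+02
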