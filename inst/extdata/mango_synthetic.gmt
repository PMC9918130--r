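ADULT_NEUROGENESIS_SYNTHETIC	synthetic stand-in for a curated adult hippocampal neurogenesis gene list (397 symbols)	Nr1d1	Fmr1	Atf2	Braf	Pten	Fxr2	Creb1	Egr1	Htr2c	Prlr	Epha5	Notch3	Slc7a11	Mif	Sng001	Sng002	Sng003	Sng004	Sng005	Sng006	Sng007	Sng008	Sng009	Sng010	Sng011	Sng012	Sng013	Sng014	Sng015	Sng016	Sng017	Sng018	Sng019	Sng020	Sng021	Sng022	Sng023	Sng024	Sng025	Sng026	Sng027	Sng028	Sng029	Sng030	Sng031	Sng032	Sng033	Sng034	Sng035	Sng036	Sng037	Sng038	Sng039	Sng040	Sng041	Sng042	Sng043	Sng044	Sng045	Sng046	Sng047	Sng048	Sng049	Sng050	Sng051	Sng052	Sng053	Sng054	Sng055	Sng056	Sng057	Sng058	Sng059	Sng060	Sng061	Sng062	Sng063	Sng064	Sng065	Sng066	Sng067	Sng068	Sng069	Sng070	Sng071	Sng072	Sng073	Sng074	Sng075	Sng076	Sng077	Sng078	Sng079	Sng080	Sng081	Sng082	Sng083	Sng084	Sng085	Sng086	Sng087	Sng088	Sng089	Sng090	Sng091	Sng092	Sng093	Sng094	Sng095	Sng096	Sng097	Sng098	Sng099	Sng100	Sng101	Sng102	Sng103	Sng104	Sng105	Sng106	Sng107	Sng108	Sng109	Sng110	Sng111	Sng112	Sng113	Sng114	Sng115	Sng116	Sng117	Sng118	Sng119	Sng120	Sng121	Sng122	Sng123	Sng124	Sng125	Sng126	Sng127	Sng128	Sng129	Sng130	Sng131	Sng132	Sng133	Sng134	Sng135	Sng136	Sng137	Sng138	Sng139	Sng140	Sng141	Sng142	Sng143	Sng144	Sng145	Sng146	Sng147	Sng148	Sng149	Sng150	Sng151	Sng152	Sng153	Sng154	Sng155	Sng156	Sng157	Sng158	Sng159	Sng160	Sng161	Sng162	Sng163	Sng164	Sng165	Sng166	Sng167	Sng168	Sng169	Sng170	Sng171	Sng172	Sng173	Sng174	Sng175	Sng176	Sng177	Sng178	Sng179	Sng180	Sng181	Sng182	Sng183	Sng184	Sng185	Sng186	Sng187	Sng188	Sng189	Sng190	Sng191	Sng192	Sng193	Sng194	Sng195	Sng196	Sng197	Sng198	Sng199	Sng200	Sng201	Sng202	Sng203	Sng204	Sng205	Sng206	Sng207	Sng208	Sng209	Sng210	Sng211	Sng212	Sng213	Sng214	Sng215	Sng216	Sng217	Sng218	Sng219	Sng220	Sng221	Sng222	Sng223	Sng224	Sng225	Sng226	Sng227	Sng228	Sng229	Sng230	Sng231	Sng232	Sng233	Sng234	Sng235	Sng236	Sng237	Sng238	Sng239	Sng240	Sng241	Sng242	Sng243	Sng244	Sng245	Sng246	Sng247	Sng248	Sng249	Sng250	Sng251	Sng252	Sng253	Sng254	Sng255	Sng256	Sng257	Sng258	Sng259	Sng260	Sng261	Sng262	Sng263	Sng264	Sng265	Sng266	Sng267	Sng268	Sng269	Sng270	Sng271	Sng272	Sng273	Sng274	Sng275	Sng276	Sng277	Sng278	Sng279	Sng280	Sng281	Sng282	Sng283	Sng284	Sng285	Sng286	Sng287	Sng288	Sng289	Sng290	Sng291	Sng292	Sng293	Sng294	Sng295	Sng296	Sng297	Sng298	Sng299	Sng300	Sng301	Sng302	Sng303	Sng304	Sng305	Sng306	Sng307	Sng308	Sng309	Sng310	Sng311	Sng312	Sng313	Sng314	Sng315	Sng316	Sng317	Sng318	Sng319	Sng320	Sng321	Sng322	Sng323	Sng324	Sng325	Sng326	Sng327	Sng328	Sng329	Sng330	Sng331	Sng332	Sng333	Sng334	Sng335	Sng336	Sng337	Sng338	Sng339	Sng340	Sng341	Sng342	Sng343	Sng344	Sng345	Sng346	Sng347	Sng348	Sng349	Sng350	Sng351	Sng352	Sng353	Sng354	Sng355	Sng356	Sng357	Sng358	Sng359	Sng360	Sng361	Sng362	Sng363	Sng364	Sng365	Sng366	Sng367	Sng368	Sng369	Sng370	Sng371	Sng372	Sng373	Sng374	Sng375	Sng376	Sng377	Sng378	Sng379	Sng380	Sng381	Sng382	Sng383
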