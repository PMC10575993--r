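MHC_CLASS_I	synthetic	IMMG229	IMMG065	IMMG153	IMMG074	IMMG228	IMMG146	IMMG122	IMMG049	IMMG128	IMMG047
MHC_CLASS_II	synthetic	IMMG071	IMMG100	IMMG089	IMMG165	IMMG110	IMMG020	IMMG154	IMMG114	IMMG111	IMMG131	IMMG041	IMMG248	IMMG027	IMMG164	IMMG229	IMMG223	IMMG109
NK_CELLS	synthetic	IMMG212	IMMG162	IMMG092	IMMG104	IMMG003	IMMG058	IMMG225	IMMG042	IMMG024	IMMG158	IMMG043	IMMG143	IMMG150	IMMG245
CD8_T_CELLS	synthetic	IMMG036	IMMG068	IMMG214	IMMG146	IMMG109	IMMG092	IMMG197	IMMG004	IMMG226	IMMG178	IMMG099	IMMG216	IMMG215	IMMG177	IMMG154	IMMG114	IMMG006
CD4_T_CELLS	synthetic	IMMG130	IMMG116	IMMG003	IMMG118	IMMG149	IMMG002	IMMG102	IMMG186	IMMG138	IMMG040	IMMG005	IMMG033	IMMG177	IMMG103	IMMG228
B_CELLS	synthetic	IMMG073	IMMG157	IMMG076	IMMG212	IMMG009	IMMG235	IMMG035	IMMG221	IMMG016	IMMG101	IMMG220	IMMG238	IMMG069	IMMG240	IMMG118	IMMG130	IMMG082	IMMG152	IMMG113
T_HELPER_CELLS	synthetic	IMMG069	IMMG110	IMMG104	IMMG183	IMMG040	IMMG149	IMMG228	IMMG057	IMMG100	IMMG231	IMMG042
TREG_CELLS	synthetic	IMMG091	IMMG013	IMMG181	IMMG054	IMMG083	IMMG032	IMMG208	IMMG060	IMMG029	IMMG081	IMMG108
DENDRITIC_CELLS	synthetic	IMMG121	IMMG085	IMMG126	IMMG171	IMMG186	IMMG112	IMMG072	IMMG029	IMMG183	IMMG166	IMMG001	IMMG141	IMMG206	IMMG133	IMMG201	IMMG055	IMMG144	IMMG218
MACROPHAGES	synthetic	IMMG042	IMMG250	IMMG248	IMMG097	IMMG185	IMMG157	IMMG025	IMMG115	IMMG191	IMMG032	IMMG081	IMMG238	IMMG014	IMMG111	IMMG006	IMMG175	IMMG043	IMMG190	IMMG165	IMMG208
MAST_CELLS	synthetic	IMMG246	IMMG113	IMMG242	IMMG031	IMMG162	IMMG094	IMMG224	IMMG006	IMMG214	IMMG038
NEUTROPHILS	synthetic	IMMG084	IMMG015	IMMG034	IMMG170	IMMG215	IMMG188	IMMG012	IMMG128	IMMG154	IMMG041	IMMG193	IMMG066	IMMG056	IMMG152	IMMG098
EOSINOPHILS	synthetic	IMMG092	IMMG107	IMMG061	IMMG190	IMMG014	IMMG162	IMMG124	IMMG194	IMMG095	IMMG032	IMMG155	IMMG138	IMMG185	IMMG028	IMMG118	IMMG037	IMMG239	IMMG113
TH1_SIGNATURE	synthetic	IMMG005	IMMG035	IMMG078	IMMG014	IMMG156	IMMG122	IMMG097	IMMG229	IMMG227	IMMG182
TH2_SIGNATURE	synthetic	IMMG127	IMMG031	IMMG237	IMMG043	IMMG180	IMMG224	IMMG081	IMMG187	IMMG027	IMMG030	IMMG246	IMMG100	IMMG212	IMMG075	IMMG209	IMMG201	IMMG145	IMMG062	IMMG013
TH17_SIGNATURE	synthetic	IMMG061	IMMG116	IMMG001	IMMG145	IMMG161	IMMG028	IMMG002	IMMG159	IMMG136	IMMG127
CYTOLYTIC_ACTIVITY	synthetic	IMMG229	IMMG013	IMMG012	IMMG193	IMMG158	IMMG051	IMMG188	IMMG095	IMMG165	IMMG047	IMMG056	IMMG198
INTERFERON_GAMMA_RESPONSE	synthetic	IMMG144	IMMG010	IMMG199	IMMG201	IMMG233	IMMG153	IMMG003	IMMG082	IMMG181	IMMG239	IMMG028	IMMG207	IMMG093	IMMG057	IMMG084	IMMG217
CHEMOKINES	synthetic	IMMG216	IMMG225	IMMG061	IMMG102	IMMG171	IMMG233	IMMG150	IMMG154	IMMG182	IMMG054	IMMG212	IMMG055	IMMG241	IMMG058	IMMG173
CHEMOKINE_RECEPTORS	synthetic	IMMG043	IMMG207	IMMG085	IMMG162	IMMG153	IMMG102	IMMG193	IMMG142	IMMG240	IMMG049	IMMG139	IMMG156	IMMG018	IMMG055
COSTIMULATORY_MOLECULES	synthetic	IMMG250	IMMG170	IMMG036	IMMG148	IMMG207	IMMG189	IMMG071	IMMG113	IMMG027	IMMG094	IMMG133
COINHIBITORY_MOLECULES	synthetic	IMMG148	IMMG114	IMMG169	IMMG139	IMMG220	IMMG038	IMMG106	IMMG201	IMMG127	IMMG151	IMMG090	IMMG115	IMMG105	IMMG011	IMMG147
ANTIGEN_PRESENTATION	synthetic	IMMG036	IMMG170	IMMG214	IMMG217	IMMG182	IMMG059	IMMG113	IMMG030	IMMG187	IMMG213	IMMG108	IMMG149	IMMG198	IMMG047
T_CELL_ACTIVATION	synthetic	IMMG202	IMMG088	IMMG114	IMMG183	IMMG135	IMMG142	IMMG012	IMMG181	IMMG051	IMMG010	IMMG121	IMMG089	IMMG037	IMMG194	IMMG163	IMMG162	IMMG027	IMMG046
T_CELL_EXHAUSTION	synthetic	IMMG208	IMMG100	IMMG120	IMMG053	IMMG024	IMMG166	IMMG244	IMMG213	IMMG148	IMMG203	IMMG225	IMMG123	IMMG206	IMMG092	IMMG033	IMMG093	IMMG036	IMMG045	IMMG096	IMMG102
IMMUNE_CHECKPOINT	synthetic	IMMG172	IMMG192	IMMG135	IMMG108	IMMG005	IMMG159	IMMG160	IMMG210	IMMG167	IMMG141	IMMG122	IMMG030	IMMG054	IMMG002	IMMG028
TUMOR_INFILTRATING_LYMPHOCYTES	synthetic	IMMG161	IMMG111	IMMG221	IMMG212	IMMG235	IMMG009	IMMG054	IMMG138	IMMG199	IMMG115	IMMG220	IMMG082
INFLAMMATION_PROMOTING	synthetic	IMMG108	IMMG202	IMMG073	IMMG147	IMMG079	IMMG046	IMMG131	IMMG150	IMMG061	IMMG020	IMMG170	IMMG098	IMMG215	IMMG017	IMMG082	IMMG211	IMMG174	IMMG237
PARAINFLAMMATION	synthetic	IMMG165	IMMG173	IMMG178	IMMG179	IMMG243	IMMG074	IMMG048	IMMG162	IMMG186	IMMG068	IMMG217	IMMG090	IMMG061	IMMG231	IMMG161	IMMG110	IMMG116	IMMG214	IMMG108
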