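assay	position	base	genes	tier
2DL2-001	93	T	2DL2	primary
2DL2-001	93	C	2DL3,2DS2,2DP1	shared
2DL2-001	137	C	2DS2,2DL2,2DL3	shared
2DL2-001	137	T	2DP1	secondary
2DL2-001	206	A	2DL2,2DL3	shared
2DL2-001	206	C	2DP1	shared
2DL2-001	206	G	2DS2	shared
2DL2-001	209	T	2DS2	secondary
2DL2-001	209	C	2DL2,2DL3,2DP1	shared
2DL3-006	136	G	2DL3	primary
2DL3-006	136	T	2DS3,2DS5	shared
2DL3-006	616	T	2DL3	primary
2DL3-006	616	C	2DS3,2DS5	shared
2DL3-006	59	A	2DS3,2DS5	secondary
2DL3-006	59	G	2DL3	shared
2DL5	170	G	2DL5	primary
2DL5	170	C	2DL4,3DP1	shared
2DL5	170	T	2DL1	shared
2DL5	174	A	2DL5	primary
2DL5	174	C	2DL4,3DP1	shared
2DL5	58	G	2DL5	secondary
2DL5	58	A	2DL4,3DP1	shared
2DL5	79	T	2DL5	secondary
2DL5	79	C	2DL4,3DP1	shared
2DL5	103	C	2DL5	secondary
2DL5	103	T	2DL4,3DP1	shared
2DL5	157	A	2DL5	secondary
2DL5	157	G	2DL4,3DP1	shared
2DP1-002	128	G	2DP1	primary
2DP1-002	130	A	2DP1	primary
2DS2-002	89	A	2DS2	primary
2DS2-002	89	G	2DL1,2DL2,2DL3	shared
2DS2-002	60	A	2DL1	secondary
2DS2-002	60	G	2DL2,2DL3,2DS2	shared
2DS2-002	117	A	2DL1	secondary
2DS2-002	117	C	2DL2,2DL3,2DS2	shared
2DS2-002	154	A	2DL1	secondary
2DS2-002	154	T	2DL2,2DL3,2DS2	shared
2DS35-005	247	T	2DS3,2DS5	primary
2DS35-005	247	C	2DS1	shared
2DS35-005	251	G	2DS3,2DS5	primary
2DS35-005	251	A	2DS1	shared
2DS35-005	403	A	2DS3,2DS5	primary
2DS35-005	403	G	2DS1	shared
2DS35-005	404	T	2DS3,2DS5	primary
2DS35-005	404	C	2DS1	shared
2DS35-005	446	G	2DS3	primary
2DS35-005	446	A	2DS1	secondary
2DS35-005	446	T	2DS5	shared
2DS35-005	507	T	2DS3	primary
2DS35-005	507	C	2DS1,2DS5	shared
2DS35-005	376	C	2DS5	primary
2DS35-005	376	T	2DS1,2DS3	shared
2DS35-005	447	A	2DS5	primary
2DS35-005	447	G	2DS1,2DS3	shared
3DL1-002	85	T	3DL1	primary
3DL1-002	85	G	3DS1	primary
3DL1-005	157	C	3DL1	primary
3DL1-005	157	T	3DS1	primary
3DL1-005	167	T	3DL1	primary
3DL1-005	167	G	3DS1	primary
KIR-2DL2-N1	126	G	2DL2	primary
KIR-2DL2-N1	126	A	2DL3,2DS2,2DP1	shared
KIR-2DL2-N1	213	A	2DS2	secondary
KIR-2DL2-N1	213	G	2DL2,2DL3,2DP1	shared
KIR-2DL2-N1	217	C	2DP1	secondary
KIR-2DL2-N1	217	T	2DL2,2DL3,2DS2	shared
KIR-2DS2-N1	92	T	2DS2	primary
KIR-2DS2-N1	92	C	2DL2,2DL3,2DP1	shared
KIR-2DS2-N1	179	T	2DL2	secondary
KIR-2DS2-N1	179	C	2DL3,2DS2,2DP1	shared
2DS1-4-002	257	A	2DS1	primary
2DS1-4-002	257	C	2DL1	primary
2DS1-4-002	257	T	2DS4	primary
2DS1-4-002	86	T	2DS4	primary
2DS1-4-002	86	C	2DS1,2DL1	shared
2DS1-4-002	95	A	2DS4	primary
2DS1-4-002	95	G	2DS1,2DL1	shared
2DS1-4-002	76	T	2DS4	secondary
2DS1-4-002	76	A	2DS1,2DL1	shared
2DS1-4-002	138	G	2DS4	secondary
2DS1-4-002	138	A	2DS1,2DL1	shared
2DS1-004	80	A	2DS1	primary
2DS1-004	80	C	2DL1	primary
2DS1-004	139	G	2DL1	secondary
2DS1-004	139	T	2DS1	secondary
3DL1-3DS1-01	300	A	3DL1,3DS1	shared
3DL1-3DS1-01	300	G	3DL2	secondary
3DL1-3DS1-05	310	C	3DL1,3DS1	shared
3DL1-3DS1-05	310	T	3DL2	secondary
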