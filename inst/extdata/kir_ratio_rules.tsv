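assay	num_genes	den_genes	num_position	num_base	den_position	den_base	classes
2DL2-001	2DS2,2DL2,2DL3	2DP1	137	C	137	T	1:1,2:1,3:1,3:2,4:1
2DL2-001	2DL2,2DL3	2DP1	206	A	206	C	1:1,2:1
2DL2-001	2DL2,2DL3	2DS2	206	A	209	T	1:1,2:1
2DL3-006	2DL3	2DS3,2DS5	136	G	136	T	1:1,2:1,1:2
2DL5	2DL5	2DL4,3DP1	170	G	170	C	any
2DS35-005	2DS1	2DS3	446	A	446	G	1:1,1:2
2DS35-005	2DS3	2DS5	446	G	447	A	1:1,2:1,1:2
3DL1-005	3DL1	3DS1	167	T	167	G	1:1
KIR-2DL2-N1	2DS2	2DP1	213	A	217	C	1:1,1:2
3DL1-3DS1-01	3DL1,3DS1	3DL2	300	A	300	G	1:1,0:2,1:2,3:2
3DL1-3DS1-05	3DL1,3DS1	3DL2	310	C	310	T	1:1,0:2,1:2,3:2
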