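name	cen_motif	tel_motif	submotifs	partial_3DL2	3DL3	2DS2	2DL2	2DL3	2DL5	2DS35	2DP1	2DL1	3DP1	2DL4	3DL1	3DS1	2DS1	2DS4	3DL2	2DS2.S3	2DP1.L1	2DL1.S1	3DL1.L2	frequency
cA01|tA01	cA01	tA01	.	0	1	0	0	1	0	0	1	1	1	1	1	0	0	1	1	0	0	0	0	0.529122698959
cA01|tB01	cA01	tB01	.	0	1	0	0	1	1	1	1	1	1	1	0	1	1	0	1	0	0	0	0	0.140607534596
cB01|tA01	cB01	tA01	.	0	1	1	1	0	1	1	1	1	1	1	1	0	0	1	1	0	0	0	0	0.091309833751
cB01|tB01	cB01	tB01	.	0	1	1	1	0	2	2	1	1	1	1	0	1	1	0	1	0	0	0	0	0.024264410945
cB02|tA01	cB02	tA01	.	0	1	1	1	0	0	0	0	0	1	1	1	0	0	1	1	0	0	0	0	0.117477413813
cB02|tB01	cB02	tB01	.	0	1	1	1	0	1	1	0	0	1	1	0	1	1	0	1	0	0	0	0	0.031218107935
cB03|tA01	cB03	tA01	.	0	1	0	0	1	1	1	1	1	1	1	1	0	0	1	1	0	0	0	0	0.002400000000
cB01|tA01-del3	cB01	tA01	del3	0	1	0	1	0	1	1	1	1	1	1	1	0	0	1	1	0	0	0	0	0.001350000000
cB02|tA01-del3	cB02	tA01	del3	0	1	0	1	0	0	0	0	0	1	1	1	0	0	1	1	0	0	0	0	0.001350000000
cB01|tA01-del4	cB01	tA01	del4	0	1	1	0	0	1	1	1	1	1	1	1	0	0	1	1	0	0	0	0	0.000200000000
cB01|tA01-del9	cB01	tA01	del9	0	1	1	1	0	0	0	0	1	1	1	1	0	0	1	1	0	0	0	0	0.000200000000
cB01|tA01-del10	cB01	tA01	del10	0	1	0	0	0	0	0	1	1	1	1	1	0	0	1	1	1	0	0	0	0.001900000000
cA01|tA01-hybd1	cA01	tA01	hybd1	0	1	0	0	1	0	0	1	1	1	1	0	0	0	0	0	0	0	0	1	0.003900000000
cA01|tA01-del5	cA01	tA01	del5	0	1	0	0	1	0	0	1	1	0	0	0	0	0	1	1	0	0	0	0	0.000550000000
cB01|tA01-del5	cB01	tA01	del5	0	1	1	1	0	1	1	1	1	0	0	0	0	0	1	1	0	0	0	0	0.000550000000
cA01|tB01-del6	cA01	tB01	del6	0	1	0	0	1	1	1	1	1	0	0	0	0	1	0	1	0	0	0	0	0.011850000000
cB02|tB01-del6	cB02	tB01	del6	0	1	1	1	0	1	1	0	0	0	0	0	0	1	0	1	0	0	0	0	0.011850000000
cA01|tB01-del7	cA01	tB01	del7	1	1	0	0	1	0	0	1	0	0	0	0	0	0	0	1	0	0	1	0	0.002033333333
cB01|tB01-del7	cB01	tB01	del7	0	1	1	1	0	1	1	1	0	0	0	0	0	0	0	1	0	0	1	0	0.002033333333
cA01|tB01-del8	cA01	tB01	del8	0	1	0	0	1	0	0	1	0	0	0	0	0	0	0	1	0	0	1	0	0.002033333333
cA01|tA01-ins3	cA01	tA01	ins3	0	1	0	0	1	0	0	1	1	2	2	2	0	0	1	1	0	0	0	0	0.000320000000
cB01|tA01-ins3	cB01	tA01	ins3	0	1	1	1	0	1	1	1	1	2	2	2	0	0	1	1	0	0	0	0	0.000320000000
cB02|tA01-ins3	cB02	tA01	ins3	0	1	1	1	0	0	0	0	0	2	2	2	0	0	1	1	0	0	0	0	0.000320000000
cA01|tB01-ins3	cA01	tB01	ins3	0	1	0	0	1	1	1	1	1	2	2	1	1	1	0	1	0	0	0	0	0.000320000000
cB01|tB01-ins3	cB01	tB01	ins3	0	1	1	1	0	2	2	1	1	2	2	1	1	1	0	1	0	0	0	0	0.000320000000
cA01|tA01-ins4	cA01	tA01	ins4	0	1	0	0	1	0	0	1	1	2	2	1	1	0	1	1	0	0	0	0	0.002020000000
cB01|tA01-ins4	cB01	tA01	ins4	0	1	1	1	0	1	1	1	1	2	2	1	1	0	1	1	0	0	0	0	0.002020000000
cB02|tA01-ins4	cB02	tA01	ins4	0	1	1	1	0	0	0	0	0	2	2	1	1	0	1	1	0	0	0	0	0.002020000000
cA01|tB01-ins4	cA01	tB01	ins4	0	1	0	0	1	1	1	1	1	2	2	0	2	1	0	1	0	0	0	0	0.002020000000
cB01|tB01-ins4	cB01	tB01	ins4	0	1	1	1	0	2	2	1	1	2	2	0	2	1	0	1	0	0	0	0	0.002020000000
cA01|tA01-ins5	cA01	tA01	ins5	0	1	0	0	1	1	1	1	1	2	2	1	1	0	1	1	0	1	0	0	0.002100000000
cB01|tA01-ins5	cB01	tA01	ins5	0	1	1	1	0	2	2	1	1	2	2	1	1	0	1	1	0	1	0	0	0.002100000000
cB02|tA01-ins5	cB02	tA01	ins5	0	1	1	1	0	1	1	0	0	2	2	1	1	0	1	1	0	1	0	0	0.002100000000
cB03|tA01-ins5	cB03	tA01	ins5	0	1	0	0	1	2	2	1	1	2	2	1	1	0	1	1	0	1	0	0	0.002100000000
cB01|tB01-ins5	cB01	tB01	ins5	0	1	1	1	0	3	3	1	1	2	2	0	2	1	0	1	0	1	0	0	0.002100000000
cB01|tA01-del3-ins4	cB01	tA01	del3,ins4	0	1	0	1	0	1	1	1	1	2	2	1	1	0	1	1	0	0	0	0	0.000800000000
cB02|tB01-del3-del6	cB02	tB01	del3,del6	0	1	0	1	0	1	1	0	0	0	0	0	0	1	0	1	0	0	0	0	0.000800000000
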