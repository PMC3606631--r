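assay	exon	genes_amplified
2DL2-001	5	2DL2,2DL3,2DS2,2DP1,(3DL2)
2DL3-006	7/8	2DL3,2DS3,2DS5
2DL5	3	2DL1,2DL4,2DL5,3DP1
2DP1-002	3	2DP1
2DS2-002	4	2DL1,2DL2,2DL3,2DS2,3DP1
2DS35-005	4	2DS1,2DS3,2DS5,3DP1,(2DL1)
3DL1-002	4	3DL1,3DS1
3DL1-005	4	3DL1,3DS1
KIR-2DL2-N1	4	2DL2,2DL3,2DS2,2DP1
KIR-2DS2-N1	5	2DL2,2DL3,2DP1,2DS2
2DS1-4-002	4	2DS1,2DL1,2DS4,(2DS3),(2DS5)
2DS1-004	4	2DS1,2DL1,(2DS4)
3DL1-3DS1-01	4	3DL1,3DS1,3DL2
3DL1-3DS1-05	4	3DL1,3DS1,3DL2
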