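hybrid	assay	presents_as
2DS2/S3	2DL2-001	2DS2
2DS2/S3	2DS2-002	2DS2
2DS2/S3	KIR-2DL2-N1	2DS2
2DS2/S3	KIR-2DS2-N1	2DS2
2DS2/S3	2DL3-006	2DS3
2DP1/L1	2DP1-002	2DP1
2DP1/L1	2DS2-002	2DL1
2DP1/L1	2DS1-4-002	2DL1
2DP1/L1	2DS1-004	2DL1
2DL1/S1	2DL5	2DL1
2DL1/S1	2DS35-005	2DS1
2DL1/S1	2DS1-4-002	2DS1
2DL1/S1	2DS1-004	2DS1
3DL1/L2	3DL1-002	3DL1
3DL1/L2	3DL1-005	3DL1
3DL1/L2	3DL1-3DS1-01	3DL1
3DL1/L2	3DL1-3DS1-05	3DL1
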