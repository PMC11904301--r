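gene	nbl_s1	nbl_s2	nbl_s3
GPC2	10.1	9.8	10.4
CD19	4.2	3.9	4.6
ALK	8.3	8.9	8.1
EGFR	7.2	6.8	7.5
DLL3	6.6	6.1	6.9
MYC	9.4	9.1	9.7
ACTB	12.2	12.0	12.5
GAPDH	11.3	11.1	11.6
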