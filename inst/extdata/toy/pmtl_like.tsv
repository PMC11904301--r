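gene	pmtl_flag
GPC2	1
CD19	1
ALK	1
EGFR	0
DLL3	0
MYC	0
ACTB	0
GAPDH	0
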