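gene	evidence_score	compartments_score
GPC2	5	5
CD19	5	4
ALK	4	4
EGFR	4	5
DLL3	3	3
MYC	0	1
ACTB	1	0
GAPDH	0	0
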