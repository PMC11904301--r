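gene	nbl.line1	nbl.line2	lung.line1
GPC2	0.72	0.81	0.10
CD19	0.05	0.02	0.04
ALK	0.88	0.79	0.15
EGFR	0.12	0.08	0.75
DLL3	0.35	0.41	0.05
MYC	0.91	0.88	0.90
ACTB	0.22	0.18	0.20
GAPDH	0.30	0.25	0.28
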