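gene	brain	liver	lung	blood
GPC2	2.1	0.8	1.2	0.5
CD19	0.3	0.6	0.4	45.0
ALK	8.5	0.9	1.1	0.4
EGFR	60.2	35.4	80.1	5.2
DLL3	12.4	0.7	1.0	0.3
MYC	25.0	30.2	28.4	40.1
ACTB	900.5	1100.2	950.8	1200.4
GAPDH	850.3	700.9	910.6	880.2
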