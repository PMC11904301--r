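gene	phenotype	modality	status
GPC2	nbl	ADC	clinical
ALK	nbl	mAb	clinical
CD19	leukemia	CAR-T	approved
EGFR	lung	mAb	approved
DLL3	nbl	ADC	discontinued
EGFR	nbl	mAb	discontinued
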