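schema: surface_evidence
key: gene
columns:
  evidence_score: 0-5 surface-proteomics evidence score
  compartments_score: 0-5 localization confidence score
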