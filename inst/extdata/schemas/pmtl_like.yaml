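schema: pmtl_like
key: gene
columns:
  pmtl_flag: 0/1 pediatric molecular target list membership
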