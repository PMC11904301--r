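schema: drugdb
key: gene            # repeated; one row per drug record
columns:
  phenotype: cancer phenotype the record applies to (case-folded exact match)
  modality: ADC | CAR-T | mAb | other
  status: approved | clinical | discontinued
notes: >
  Phenotype-matched records derive labels (active -> positive, all
  discontinued -> negative); records in other phenotypes feed the
  has_drug / has_adc availability features.
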