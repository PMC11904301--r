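datasets:
  - path: expression.tsv
    format: tsv
    units: log2
    phenotype: nbl
snapshots:
  gtex_like: gtex_like.tsv
  surface_evidence: surface_evidence.tsv
  depmap_like: depmap_like.tsv
  pmtl_like: pmtl_like.tsv
  drugdb: drugdb.tsv
labels:
  source: drug_snapshot
optimization:
  strategy: multi_cancer
  population: 20
  generations: 20
seed: 7
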