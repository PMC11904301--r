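schema: depmap_like
key: gene
columns: one numeric dependency column per cell line, named <phenotype>.<cell_line>
units: dependency effect; higher = stronger tumor dependency
notes: >
  Derived features average columns whose phenotype prefix matches the scored
  project's phenotype (case-folded); all columns when none match.
  essentiality_frac counts lines with dependency >= 0.5.
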