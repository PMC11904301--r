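schema: gtex_like
key: gene            # uppercase HGNC-style symbol, unique
columns: one numeric column per normal tissue
units: median expression per tissue (linear scale, TPM-like)
notes: >
  Derived features: normal_expr_max (row maximum across tissues) and
  normal_expr_pctile (rank percentile of that maximum among snapshot genes).
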