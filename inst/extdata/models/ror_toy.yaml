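# Toy ROR-family risk model with lymph-node-keyed cutpoints. Illustrative
# parameters only - these are not published clinical coefficients.
name: ror_toy
family: ror
description: toy ROR model, PT form scored against LN-specific thresholds
variant: Tot
correlation_method: pearson
centering: none
centroids: ror_toy_centroids.tsv
weights: {SubA: 1.0, SubB: -1.0}
proliferation_genes: [g4, g5]
coefficients: {a: 1.0, b: 2.0, c: 0.05}
thresholds:
  LN-: [0.4, 1.2]
  LN+: [0.2, 0.9]
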