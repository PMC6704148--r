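# Toy nearest-centroid subtype model. Parameters are illustrative only and
# carry no clinical meaning.
name: centroid_toy
family: centroid_subtype
description: two-class toy centroid model over three genes
correlation_method: spearman
centering: none
classes: [ClassA, ClassB]
genes: [g1, g2, g3]
centroids:
  ClassA: {g1: 1.0, g2: 2.0, g3: 3.0}
  ClassB: {g1: 3.0, g2: 2.0, g3: 1.0}
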