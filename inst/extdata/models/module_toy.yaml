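# Toy module-score subtype tree (ER / HER2 / proliferation). Illustrative
# parameters only.
name: module_toy
family: module_subtype
description: decision tree over three module means
modules:
  er: {genes: [g1, g2], cutoff: 1.0}
  her2: {genes: [g3], cutoff: 2.0}
  proliferation: {genes: [g4, g5], cutoff: 1.5}
class_map:
  her2: HER2E
  luminal_low: LumA
  luminal_high: LumB
  basal: Basal
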