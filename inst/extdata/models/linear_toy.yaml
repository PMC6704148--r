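# Toy weighted-module linear risk model (recurrence-score form).
# Illustrative parameters only.
name: linear_toy
family: linear_risk
description: two-module toy score with one clipped module
classes: [low, intermediate, high]
modules:
  - name: m1
    genes: [g1, g2]
    beta: 2.0
  - name: m2
    genes: [g3]
    beta: -1.0
    clip: true
    tau: 0.5
intercept: 0.0
thresholds: [0.5, 2.0]
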