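# Toy correlation-to-template two-class risk model. Illustrative only.
name: template_toy
family: correlation_risk
description: good-prognosis template call at a correlation cutoff
correlation_method: pearson
classes: [low, high]
centroids:
  template: {g1: 1.0, g2: 2.0, g3: 3.0, g4: 4.0}
thresholds: [0.4]
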