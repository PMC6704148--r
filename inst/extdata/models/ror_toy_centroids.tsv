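class	g1	g2	g3	g4	g5
SubA	1.0	2.0	3.0	1.0	0.0
SubB	3.0	2.0	1.0	0.0	1.0
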