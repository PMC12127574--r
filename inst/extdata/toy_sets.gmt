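SET_A	three measured genes	g1	g2	g3
SET_B	four genes one unmeasured	g4	g5	g6	gX
SET_C	two genes	g2	g5
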