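gene_set	s1	s2	s3
SET_A	1	0.666666666666667	0
SET_B	1	0.333333333333333	0.666666666666667
SET_C	1	0.5	0
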