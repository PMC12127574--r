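gene_id	s1	s2	s3	n1	n2
g1	4	3.5	0	1	3
g2	3	2	1	2	2
g3	5	4.5	2	0	4
g4	6	5	10	5	5
g5	2	1.5	1	1	1
g6	1	0	0.5	0	0
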