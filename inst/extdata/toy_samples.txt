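s1
s2
s3
n1	normal_sample
n2
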