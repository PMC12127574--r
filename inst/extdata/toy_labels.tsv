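s1	tumor
s2	tumor
s3	tumor
n1	normal
n2	normal
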