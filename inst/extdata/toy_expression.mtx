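%%MatrixMarket matrix coordinate real general
6 5 26
1 1 4
1 2 3.5
1 4 1
1 5 3
2 1 3
2 2 2
2 3 1
2 4 2
2 5 2
3 1 5
3 2 4.5
3 3 2
3 5 4
4 1 6
4 2 5
4 3 10
4 4 5
4 5 5
5 1 2
5 2 1.5
5 3 1
5 4 1
5 5 1
6 1 1
6 2 0
6 3 0.5
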