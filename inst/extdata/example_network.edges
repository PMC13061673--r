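# 10 nodes
1 2
1 3
2 4
4 5
1 6
2 6
4 6
1 7
4 7
1 8
3 8
4 8
5 8
6 8
7 8
2 9
3 9
5 9
6 9
2 10
4 10
8 10
9 10
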