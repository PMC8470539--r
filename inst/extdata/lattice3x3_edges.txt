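# n_nodes: 9
0	1
0	2
0	3
0	6
1	2
1	4
1	7
2	5
2	8
3	4
3	5
3	6
4	5
4	7
5	8
6	7
6	8
7	8
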