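# flat column-major layout: (m0, m1, m2) per group
2
2
11
5
1
3
6
0
7
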