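response,<2y,2-5y,>=6y
0,2,5,6
1,2,1,0
2,11,3,1
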