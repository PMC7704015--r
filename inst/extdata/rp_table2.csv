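response,DOM,AR,SL,ISO
0,15,7,3,67
1,6,5,2,24
2,7,9,14,57
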