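"dose","n","N"
0.3,0,500
0.5,8,500
0.7,67,500
0.9,137,500
1.2,240,500
1.6,342,500
2.2,406,500
3,441,500
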