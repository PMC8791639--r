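spacer	penalty
7	2.2000000000000002
8	0.59999999999999998
9	0
10	0.59999999999999998
11	2.2000000000000002
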