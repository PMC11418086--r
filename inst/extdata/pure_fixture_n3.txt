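3
0 -1 0
0 0 -1
1 0 6.123233995736766e-17
0 0 -1
0 -1 0
1 6.123233995736766e-17 0
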