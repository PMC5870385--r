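tool,physician_A,physician_B,physician_C
A,42,121,8
B,6,47,2
C,0,7,4
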