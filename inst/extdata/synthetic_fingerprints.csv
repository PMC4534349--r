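s1,A,1111111100000000
s2,A,1111111100000000
s3,A,1111111100000000
s4,A,1111011100000000
s5,A,1111111100000000
s6,A,1111111100000100
s7,B,0000000011111111
s8,B,0000000011111111
s9,B,0000000011111111
s10,B,0000000011111111
s11,B,0000000011011111
s12,B,0000000011111111
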