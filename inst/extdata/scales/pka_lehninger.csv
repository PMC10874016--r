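group,value
nterm,9.69
cterm,2.34
D,3.65
E,4.25
C,8.18
Y,10.07
H,6.0
K,10.53
R,12.48
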