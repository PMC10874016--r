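residue,PP1,PP2,PP3
A,-0.96,-0.61,0.45
R,0.8,0.57,-0.32
N,0.82,-0.57,-0.02
D,1.04,-0.78,-0.14
C,-0.55,0.38,0.17
Q,0.75,-0.4,-0.02
E,0.94,-0.54,-0.23
G,-0.2,-1.54,0.27
H,0.46,0.46,0.17
I,-1.39,0.74,0.26
L,-1.36,0.67,0.29
K,0.6,0.1,-0.87
M,-1.09,0.62,0.16
F,-1.42,0.96,0.22
P,-0.4,-0.79,-0.4
S,0.33,-0.87,0.12
T,0.21,-0.7,0.2
W,-1.13,1.38,0.07
Y,-0.58,1.09,0.05
V,-1.27,0.48,0.24
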