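hg_hvr,hg_coding
U2e,U
U4,U
U4a1,U
U5a,U
U5a1,U
U5b,U
U1,U
C1,C
C*,C
C5,C
Z,M
Z1a,M
M*,M
D*,D
H,H
T*,T
J,J
K,K
W,W
X,X
I,I
V,V
HV,HV
N1,N
A,A
B,B
F,F
G,G
Y,Y
L,L
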