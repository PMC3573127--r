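hg,motif,class
L,187T-189C-223T-278T-311C,misc
C5,148T-223T-288C-298C-327T,C
Z1a,185T-223T-224C-260T-298C,Z
C1,223T-298C-325C-327T,C
Z,185T-223T-260T-298C,Z
U5a1,192T-256T-270T-399G,U5a
I,129A-223T-391A,I
X,189C-223T-278T,X
G,223T-278T-362C,EAS
A,223T-290T-319A,EAS
Y,126C-231C-266T,EAS
C*,223T-298C-327T,C
U4a1,129A-134T-356C,U4
U5a,192T-256T-270T,U5a
D*,223T-362C,D
U2e,129c-362C,U2
T*,126C-294T,T
W,223T-292T,W
N1,145A-223T,N1
K,224C-311C,K
U5b,189C-270T,U5b
B,189C-217C,EAS
J,069T-126C,J
M*,223T,misc
V,298C,V
HV,067T,HV
U4,356C,U4
F,304C,EAS
U1,249C,misc
H,,H
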