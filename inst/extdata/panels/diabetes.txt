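# Illustrative monogenic-diabetes mini-panel (compact subset)
HNF1A
HNF4A
HNF1B
GCK
INS
KCNJ11
ABCC8
PDX1
NEUROD1
TCF7L2
PPARG
IRS1
SLC2A2
WFS1
EIF2AK3
INSR
AKT2
BLK
CEL
KLF11
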