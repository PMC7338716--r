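# Illustrative neurodegenerative/psychiatric mini-panel (compact subset)
APP
PSEN1
PSEN2
MAPT
GRN
SNCA
LRRK2
PRNP
HTT
SOD1
FUS
TARDBP
PARK7
PINK1
PRKN
DRD2
COMT
MECP2
SCN1A
CACNA1A
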