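# Illustrative subset of the ACMG secondary-findings gene list (compact
# subset for examples and tests)
BRCA1
BRCA2
TP53
STK11
MLH1
MSH2
MSH6
PMS2
APC
MUTYH
MYH7
MYBPC3
TNNT2
TNNI3
LMNA
KCNQ1
KCNH2
SCN5A
RYR2
PKP2
DSP
DSG2
DSC2
LDLR
APOB
PCSK9
RET
VHL
SDHB
SDHD
TSC1
TSC2
FBN1
TGFBR1
TGFBR2
SMAD3
ACTA2
MYH11
PTEN
RB1
WT1
NF2
COL3A1
GLA
MEN1
OTC
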