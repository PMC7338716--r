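# Illustrative cardiovascular-disorder mini-panel (compact subset for
# examples and tests; not an exhaustive clinical panel)
KCNJ2
KCNQ1
KCNE1
KCNE2
KCNH2
SCN5A
ANK2
GPD1L
MYH7
MYBPC3
TNNT2
TNNI3
LMNA
DSP
PKP2
DSG2
DSC2
RYR2
CASQ2
CACNA1C
TGFBR3
FBN1
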