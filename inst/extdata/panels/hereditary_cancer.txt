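# Illustrative hereditary-cancer mini-panel (compact subset for examples
# and tests; not an exhaustive clinical panel)
BRCA1
BRCA2
CHEK2
MUTYH
APC
MLH1
MSH2
MSH6
PMS2
MLH3
TP53
PTEN
STK11
CDH1
PALB2
ATM
NBN
RAD50
BRIP1
RAD51C
MSR1
RNASEL
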