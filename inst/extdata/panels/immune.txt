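# Illustrative immune-disease mini-panel (compact subset)
BTK
WAS
CYBB
IL2RG
RAG1
RAG2
ADA
JAK3
STAT3
STAT1
FOXP3
AIRE
NLRP3
MEFV
TNFRSF1A
IL10RA
CTLA4
LRBA
DOCK8
PIK3CD
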