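MDM2
PRKN
AKT1
SMAD4
BRCA1
CTNNB1
TP53
MRE11
RAD50
TGFBR2
CDH1
CDKN2A
CHEK2
DICER1
EWSR1
FGFR2
GATA4
IDH1
LMNA
MSH2
NBN
PALB2
RAD51
RAD51D
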