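MDM2	YWHAQ
MDM2	RASSF3
MDM2	SFN
MDM2	UBE2E3
MDM2	ARRB1
MDM2	YWHAZ
PRKN	SQSTM1
PRKN	LIMK1
PRKN	PSMB4
PRKN	RHOT2
PRKN	CDK5
PRKN	ARRB1
AKT1	SFN
AKT1	HSPB1
AKT1	SMAD3
AKT1	EGLN1
AKT1	YWHAZ
SMAD4	KDM6B
SMAD4	ACVR1B
SMAD4	RAN
SMAD4	SMAD3
BRCA1	ACACA
BRCA1	TERF2IP
BRCA1	FAM111A
CTNNB1	BCL9
CTNNB1	CTNNA1
CTNNB1	PSEN2
TP53	BAK1
TP53	HSPB1
TP53	BCL2L2
MRE11	TERF2IP
MRE11	CHAMP1
RAD50	TERF2IP
RAD50	CHAMP1
TGFBR2	ACVR1B
TGFBR2	SMAD3
CDH1	CTNNA1
CDKN2A	PSMC3
CHEK2	GINS2
DICER1	TARBP2
EWSR1	EIF4H
FGFR2	YWHAZ
GATA4	FOS
IDH1	DAZAP1
LMNA	LMNB2
MSH2	FBXO5
NBN	TERF2IP
PALB2	MORF4L2
RAD51	RAD51AP1
RAD51D	AMOTL2
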