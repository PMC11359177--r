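protein_id	snr
YWHAQ	11.68431
RASSF3	9.9321
SFN	8.26526
UBE2E3	7.55273
ARRB1	7.40497
YWHAZ	6.60843
SQSTM1	13.47355
LIMK1	11.41166
PSMB4	10.03283
RHOT2	9.66055
CDK5	7.97013
HSPB1	8.24698
SMAD3	8.13051
EGLN1	7.58537
KDM6B	14.78335
ACVR1B	9.87143
RAN	9.42564
ACACA	10.60752
TERF2IP	9.37372
FAM111A	6.8921
BCL9	13.42896
CTNNA1	10.23149
PSEN2	8.155
BAK1	16.43688
BCL2L2	7.12573
CHAMP1	9.33687
PSMC3	7.13755
GINS2	6.01104
TARBP2	6.7722
EIF4H	10.70126
FOS	11.15809
DAZAP1	10.26606
LMNB2	11.67122
FBXO5	8.00492
MORF4L2	8.04956
RAD51AP1	14.51291
AMOTL2	7.63458
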