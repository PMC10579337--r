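gene
C20orf24
CCNB2
CCT5
CDC45
CDC2
ESPL1
FEN1
FOXM1
H2AFZ
KIF20A
MAD2L1
MCM2
MCM7
MELK
NCAPD2
PCNA
PRC1
RAD51AP1
RFC4
RNASEH2A
TOP2A
TPX2
TRIP13
TTK
UBE2C
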