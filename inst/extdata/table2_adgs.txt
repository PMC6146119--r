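AKT2
ARID5B
ATAD3A
ATG12
ATG13
ATG3
ATG5
ATG7
BAX
BCL2
BECN1
BNIP3
BNIP3L
CD80
CDKN1B
CEP55
CHMP2B
CIC
CISD2
DEPTOR
DISC1
DRAM1
EI24
EPG5
EPHB2
FOXO1
GABARAP
GABARAPL1
GABARAPL3
GBP1
GBP6
GBP7
HDAC3
HDAC5
HMGN5
KL
LMNA
LRRK2
MCL1
MEG3
MTM1
MTMR14
MTOR
NOD2
OPA1
PINK1
PTEN
RAB25
RB1CC1
RHBDF1
SLC6A14
SOX1
TET3
ULK1
UVRAG
VCP
VMA21
VMP1
WDR45
WIPI1
WRN
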