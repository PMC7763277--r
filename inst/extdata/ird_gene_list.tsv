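gene
ABCA4
AIPL1
BBS10
BEST1
CA4
CACNA1F
CDH23
CEP290
CHM
CNGA3
CNGB3
CRB1
CRX
ELOVL4
EYS
FAM161A
FSCN2
GUCY2D
IMPDH1
IMPG2
KCNV2
KLHL7
MFRP
MYO7A
NDP
NR2E3
NYX
OPA1
PCDH15
PDE6A
PDE6B
PGK1
PROM1
PRPF31
PRPF8
PRPH2
PRPS1
RDH5
RHO
RLBP1
RP1
RP1L1
RP2
RP9
RPE65
RPGR
RPGRIP1
RS1
SAG
SEMA4A
SNRNP200
TIMM8A
TIMP3
TOPORS
USH1C
USH2A
WHRN
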