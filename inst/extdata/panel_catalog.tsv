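# cardioTriage panel catalog v1.0: gene <TAB> comma-separated association tags
# tags: DCM, HCM, ARVC, channelopathy
ABCC9	DCM
ACTC1	HCM,DCM
ACTN2	DCM,HCM
AKAP9	channelopathy
ALPK3	HCM
ANK2	channelopathy
ANKRD1	DCM,HCM
BAG3	DCM
CACNA1C	channelopathy
CACNA2D1	channelopathy
CACNB2	channelopathy
CALM1	channelopathy
CALM2	channelopathy
CALM3	channelopathy
CASQ2	channelopathy
CAV3	HCM
CDH2	ARVC
CHRM2	DCM
CRYAB	DCM
CSRP3	DCM,HCM
CTF1	DCM
CTNNA3	ARVC
DES	DCM,ARVC
DLG1	channelopathy
DMD	DCM
DOLK	DCM
DSC2	ARVC
DSG2	ARVC
DSP	DCM,ARVC
DTNA	ARVC,DCM
EMD	DCM
EYA4	DCM
FHL1	HCM
FHL2	DCM
FKTN	DCM
FLNC	DCM,HCM
GATA4	DCM
GATAD1	DCM
GJA5	channelopathy
GLA	HCM
GPD1L	channelopathy
HCN4	channelopathy
ILK	DCM
JPH2	HCM
JUP	ARVC
KCNA5	channelopathy
KCND3	channelopathy
KCNE1	channelopathy
KCNE2	channelopathy
KCNE3	channelopathy
KCNH2	channelopathy
KCNJ2	channelopathy
KCNJ5	channelopathy
KCNJ8	channelopathy
KCNQ1	channelopathy
LAMA4	DCM
LAMP2	HCM
LDB3	DCM
LMNA	DCM
LRRC10	DCM
MIB1	DCM
MURC	DCM
MYBPC3	HCM,DCM
MYH6	HCM,DCM
MYH7	HCM,DCM
MYL2	HCM
MYL3	HCM
MYLK2	HCM
MYO6	DCM
MYOZ2	HCM
MYPN	DCM,HCM
NEBL	DCM
NEXN	DCM,HCM
NKX2-5	DCM
NUP155	channelopathy
OBSCN	HCM,DCM
PDLIM3	DCM
PKP2	ARVC
PKP4	ARVC
PLN	DCM,HCM
PRDM16	DCM
PRKAG2	HCM
PSEN1	DCM
PSEN2	DCM
PTPN11	HCM
RAF1	HCM
RANGRF	channelopathy
RBM20	DCM
RYR2	ARVC,channelopathy
SCN1B	channelopathy
SCN2B	channelopathy
SCN3B	channelopathy
SCN4B	channelopathy
SCN5A	DCM,channelopathy
SDHA	DCM
SGCB	DCM
SGCD	DCM
SNTA1	channelopathy
SYNE1	DCM
SYNE2	DCM
TAZ	DCM
TBX20	DCM
TCAP	DCM,HCM
TGFB3	ARVC
TMEM43	ARVC
TMPO	DCM
TNNC1	HCM,DCM
TNNI3	HCM,DCM
TNNT2	HCM,DCM,ARVC
TPM1	HCM,DCM
TRDN	channelopathy
TRIM63	HCM
TRPM4	channelopathy
TTN	DCM,HCM,ARVC
VCL	DCM,HCM
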