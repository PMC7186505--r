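gene	locus	methods
LPL	8p21.3	Sherlock;GWAB;TWAS;DEPICT;DAPPLE
COL4A2	13q34	NetWAS;GWAB;DEPICT;DAPPLE
PLG	6q26	GWAB;DEPICT;DAPPLE;prix fixe
CDKN2B	9p21.3	TWAS;DEPICT;prix fixe
COL4A1	13q34	GWAB;DEPICT;DAPPLE
FES	15q26.1	Sherlock;DEPICT;DAPPLE
FLT1	13q12.3	GWAB;DEPICT;DAPPLE
FN1	2q35	GWAB;DEPICT;DAPPLE
IL6R	1q21.3	SMR (Pavlides);DEPICT;DAPPLE
LPA	6q26	DEPICT;DAPPLE;prix fixe
PCSK9	1p32.3	DEPICT;DAPPLE;prix fixe
PSRC1	1p13.3	Sherlock;SMR;TWAS
SMAD3	15q22.33	GWAB;DEPICT;DAPPLE
SWAP70	11p15.4	SMR;SMR (Pavlides);DEPICT
VAMP8	2p11.2	SMR (Pavlides);DEPICT;DAPPLE
ABCG5	2p21	GWAB;DAPPLE
ABCG8	2p21	GWAB;DAPPLE
ABO	9q34.2	Sherlock;TWAS
ACAD10	12q24.12	GWAB;TWAS
ALDH2	12q24.12	GWAB;DEPICT
APOA1	11q23.3	DEPICT;DAPPLE
APOB	2p24.1	DEPICT;DAPPLE
ARNTL	11p15.3	DEPICT;DAPPLE
ATXN2	12q24.12	GWAB;DEPICT
CABIN1	22q11.23	Sherlock;DEPICT
CETP	16q13	DEPICT;DAPPLE
CXCL12	10q11.21	DEPICT;DAPPLE
EDNRA	4q31.22	DEPICT;DAPPLE
EPOR	19p13.2	TWAS;DEPICT
FURIN	15q26.1	DEPICT;DAPPLE
GGCX	2p11.2	Sherlock;DAPPLE
GIGYF2	2q37.1	DEPICT;DAPPLE
HNRNPUL1	19q13.2	NetWAS;DEPICT
ITGB5	3q21.2	DEPICT;DAPPLE
LDLR	19p13.2	DEPICT;DAPPLE
LIPA	10q23.31	Sherlock;SMR
MAP3K4	6q26	DEPICT;prix fixe
MRAS	3q22.3	TWAS;DAPPLE
NOS3	7q36.1	DEPICT;DAPPLE
NRP1	10p11.22	NetWAS;DEPICT
NT5C2	10q24.33	Sherlock;SMR
PEMT	17p11.2	DEPICT;DAPPLE
PPAP2B	1p32.2	DEPICT;DAPPLE
PTPN11	12q24.13	GWAB;DEPICT
REST	4q12	DEPICT;DAPPLE
RHOA	3p21.31	DEPICT;DAPPLE
RRBP1	20p12.1	NetWAS;DEPICT
SH2B3	12q24.12	DEPICT;DAPPLE
SMG6	17p13.3	DEPICT;DAPPLE
SOD2	6q25.3	DEPICT;prix fixe
SVEP1	9q31.3	DEPICT;DAPPLE
TGFB1	19q13.2	DEPICT;DAPPLE
TRIB1	8q24.13	DEPICT;DAPPLE
UBE2Z	17q21.32	DEPICT;DAPPLE
ZEB2	2q22.3	DEPICT;DAPPLE
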