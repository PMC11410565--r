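gene	adult_alleles	longevity_alleles
TSC2	17	1
NF2	3	NA
TSC1	7	NA
RET	6	NA
RB1	0	1
APC	14	NA
MEN1	18	NA
SMAD4	5	NA
STK11	1	NA
WT1	10	1
MSH2	48	3
BMPR1A	1	NA
MAX	0	NA
TP53	20	8
MSH6	77	NA
PTEN	10	1
MLH1	20	NA
BRCA2	250	3
SDHD	10	3
SDHB	21	1
BRCA1	140	6
VHL	70	3
PALB2	127	3
TMEM127	12	NA
MUTYH	738	17
SDHC	13	NA
PMS2	26	3
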