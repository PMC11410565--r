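gene	pli	loeuf
TSC2	1	0.074
NF2	1	0.086
TSC1	1	0.118
RET	1	0.123
RB1	1	0.126
APC	1	0.161
MEN1	1	0.171
SMAD4	1	0.222
STK11	0.99	0.245
WT1	1	0.247
MSH2	0.9	0.334
BMPR1A	0.9	0.335
MAX	0.83	0.462
TP53	0.53	0.469
MSH6	0	0.498
PTEN	0.26	0.507
MLH1	0	0.575
BRCA2	0	0.635
SDHD	0.34	0.731
SDHB	0	0.825
BRCA1	0	0.915
VHL	0.08	0.927
PALB2	0	1.006
TMEM127	0.01	1.154
MUTYH	0	1.191
SDHC	0	1.256
PMS2	0	1.266
SDHAF2	0	1.51
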