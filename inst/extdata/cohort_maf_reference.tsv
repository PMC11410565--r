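gene	interpretation	rsid	hgvs_g	ac	n_het	n_hom	maf_printed	gnomad_af
MUTYH	LP	rs36053993	NC_000001.11:g.45331556C>T	441	439	2	0.0052	0.0032
MUTYH	LP	rs34612342	NC_000001.11:g.45332803T>C	113	113	0	0.00075	0.0015
MUTYH	LP	rs140342925	NC_000001.11:g.45332445C>T	92	92	0	0.00061	9.701e-05
VHL	LP	rs1346312258	NC_000003.12:g.10142957T>C	49	49	0	0.00033	NA
PALB2	P	rs180177102	NC_000016.10:g.23634957del	27	27	0	0.00018	9.684e-05
SDHD	VUS	rs104894302	NC_000011.10:g.112089002A>G	26	26	0	0.00017	NA
PALB2	P	rs515726123	NC_000016.10:g.23636037_23636038del	25	25	0	0.00017	NA
BRCA1	P	rs28897672	NC_000017.11:g.43106487A>C	23	23	0	0.00015	NA
MSH2	VUS	rs1194793421	NC_000002.12:g.47414419del	22	22	0	0.00015	NA
PALB2	P	rs180177143	NC_000016.10:g.23637886_23637887del	20	20	0	0.00013	6.457e-05
PMS2	VUS	rs200029834	NC_000007.14:g.6002670G>C	18	18	0	0.00012	0.0002
BRCA2	P	rs746229647	NC_000013.11:g.32338202_32338203del	17	17	0	0.00011	3.237e-05
BRCA2	P	rs80358754	NC_000013.11:g.32339641T>G	17	17	0	0.00011	NA
BRCA1	P	rs80357711	NC_000017.11:g.43091497del	16	16	0	0.00011	0.0002
MUTYH	VUS	NA	NC_000001.11:g.45331234C>T	15	15	0	0.0001	NA
MUTYH	P	rs587780088	NC_000001.11:g.45334493G>A	15	15	0	0.0001	NA
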