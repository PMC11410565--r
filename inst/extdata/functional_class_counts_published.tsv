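cohort	functional_class	pv_lpv_registered	del_vus_registered	del_vus_novel
adult	nonsynonymous_SNV	63	17	6
adult	stop_gain	94	0	45
adult	frameshift_deletion	75	13	62
adult	frameshift_insertion	22	3	40
adult	splice_site	24	8	27
longevity	nonsynonymous_SNV	9	5	0
longevity	stop_gain	5	1	3
longevity	frameshift_deletion	5	2	2
longevity	frameshift_insertion	1	0	2
longevity	splice_site	1	0	1
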