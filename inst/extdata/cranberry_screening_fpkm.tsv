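family	gene_id	length	w_fpkm	r_fpkm	published_abs_log2ratio
ACTIN	CL7164.Contig7_All	649	31.4889	33.5053	0.089545964
CYP 2	CL4850.Contig1_All	838	738.7621	747.7516	0.017449237
EF-1a	Unigene457_All	486	7.4777	7.4412	0.007059297
F-box	Unigene5822_ALL	1024	17.5606	17.7489	0.015387477
GAPDH	Unigene20107_All	1383	3.9587	3.8218	0.050774458
18S rRNA	Unigene320_All	1490	13.6523	13.9093	0.026905794
PP2A	Unigene21533_All	1452	36.0478	35.7313	0.012722810
RH 8	Unigene16896_All	1455	23.8742	24.6959	0.048819156
SAND	CL5626.Contig1_All	2158	10.4761	10.3343	0.019661066
TUBB	Unigene2152_All	838	15.3193	15.0491	0.025673166
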