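gene	mean_ct	sd	cv_pct
ACTIN	25.89	2.07	8.01
CYP 2	20.84	1.27	6.08
EF-1a	24.76	1.57	6.35
F-box	30.56	1.48	4.84
GAPDH	28.96	2.12	7.31
18S rRNA	27.20	1.18	4.35
PP2A	26.37	1.44	5.47
RH 8	27.13	1.44	5.32
SAND	28.42	1.54	5.41
TUBB	26.84	1.92	7.15
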