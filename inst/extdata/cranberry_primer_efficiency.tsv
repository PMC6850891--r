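gene	efficiency_pct	r_squared
ACTIN	97.4	0.999
CYP 2	102.4	0.998
EF-1a	99.3	0.999
F-box	104.6	0.997
GAPDH	98.5	1.000
18S rRNA	99.9	0.999
PP2A	101.3	0.999
RH 8	102.4	0.999
SAND	97.4	0.998
TUBB	101.7	0.998
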