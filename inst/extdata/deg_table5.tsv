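locus_tag	gene	base_mean	log2fc	pvalue
b1525	sad	222.2	1.32	0.022
b1526	yneJ	26.1	-6.69	0.0003
b1527	yneK	14.1	2.78	0.032
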