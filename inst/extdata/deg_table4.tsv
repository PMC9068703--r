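locus_tag	gene	base_mean	log2fc	pvalue
b0123	cueO	178	1.8	1.53E-04
b0484	copA	521	1.8	3.00E-05
b0570	cusS	112	2.2	4.39E-04
b0571	cusR	181	2.5	2.97E-05
b0572	cusC	949	7.8	1.42E-05
b0574	cusB	208	6.0	3.81E-05
b0575	cusA	281	4.8	6.52E-05
b0778	bioD1	126	-1.4	1.11E-04
b1297	puuA	706	1.9	4.64E-07
b1298	puuD	337	1.9	6.21E-05
b1299	puuR	113	1.3	9.24E-05
b1302	puuE	161	1.6	3.16E-04
b1495	nuoK	73	-1.9	4.59E-07
b1496	yddA	63	-2.3	1.25E-06
b1526	yneJ	26	-6.2	9.41E-06
b1596	ynfM	221	-1.5	3.06E-04
b1656	sodB	323	4.8	5.46E-05
b1717	rpmI	55	2.4	3.57E-05
b1886	tar	298	1.4	4.20E-05
b1889	motB	61	1.6	3.08E-04
b2094	gatA	1719	-1.4	6.09E-05
b2106	rsnA	323	-1.5	5.47E-07
b3858	yihD	42	2.6	1.29E-06
b3938	metJ	191	1.4	3.84E-04
b4142	groS	197	1.9	1.40E-04
b4207	fklB	539	1.5	2.03E-05
b4314	fimA	1118	1.4	3.46E-04
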