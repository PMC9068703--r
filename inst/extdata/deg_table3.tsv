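locus_tag	gene	base_mean	log2fc	pvalue
b3584	yiaT	26	2.8	9.32E-07
b1787	yeaK	57	-4.4	6.57E-10
b2036	glf	2378	-2.6	1.01E-09
b2035	wbbH	694	-1.9	1.63E-07
b3714	adeP	357	-1.32	7.68E-05
b3213	gltD	3158	-1.27	0.000187
b2028	ugd	374	-1.27	0.00553
b3624	waaZ	121	-1.79	5.06E-05
b3625	waaY	178	-1.77	2.08E-05
b3622	waaL	352	-2.81	3.53E-08
b3623	waaU	129	-1.72	3.98E-05
b3629	waaS	263	-2.57	1.84E-08
b3631	waaG	140	-1.61	8.90E-05
b3630	waaP	199	-1.44	0.00168
b3627	waaO	199	-1.22	0.003191
b3628	waaB	168	-1.76	3.78E-05
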