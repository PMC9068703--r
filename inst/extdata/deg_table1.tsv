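locus_tag	gene	base_mean	log2fc	pvalue
b2289	lrhA	145	-4.3	3.89E-26
b1496	yddA	13	-3.2	0.000511
b4462	ygaQ	15	-3.0	4.66E-05
b2368	emrK	16	-2.8	0.000211
b2273	yfbN	16	-2.5	0.000348
b2845	yqeG	24	-2.5	2.13E-05
b2373	oxc	1	-2.1	0.000951
b4660_1	yhiL	28	-2.0	0.000401
b2310	argT	761	-1.8	0.000795
b2349	intS	101	-1.6	0.000511
b3043	ygiL	0	-1.6	0.001001
b2309	hisJ	216	-1.4	0.000348
b1025	dgcT	122	-1.4	0.001038
b0854	potF	400	-1.4	0.000346
b2306	hisP	264	-1.4	4.90E-05
b0287	yagU	870	-1.2	0.000166
b0641	lptE	146	1.2	0.000226
b4316	fimC	168	1.2	2.37E-05
b0605	ahpC	585	1.2	5.59E-07
b4315	fimI	291	1.3	0.000279
b0622	pagP	45	1.6	7.10E-05
b2013	yeeE	315	1.7	0.000163
b1729	tcyP	655	1.8	0.000397
b2423	cysW	110	2.0	5.00E-05
b2424	cysU	245	2.0	1.29E-05
b1950	fliR	20	2.3	0.000674
b2751	cysN	297	2.4	2.77E-08
b1879	flhA	190	2.5	1.37E-09
b2752	cysD	249	2.5	2.03E-08
b0601	ybdM	20	2.5	0.000248
b2764	cysJ	381	2.6	1.62E-08
b2750	cysC	162.1	2.6	1.34E-08
b4110	yjcZ	351.3	2.7	2.81E-08
b2422	cysA	296	2.7	4.46E-08
b2763	cysI	567	2.8	3.02E-09
b1070	flgN	338	2.9	2.32E-06
b1880	flhB	118	3.0	4.53E-10
b1071	flgM	86	3.0	7.52E-05
b1946	fliN	30	3.1	1.42E-05
b1566	flxA	402	3.1	8.91E-06
b2762	cysH	145	3.2	3.14E-09
b3525	pdeH	176	3.3	6.75E-11
b1072	flgA	225	3.3	4.65E-13
b0615	citF	20	3.3	3.40E-08
b1941	fliI	165	3.4	1.66E-11
b1948	fliP	40	3.5	2.90E-10
b1081	flgJ	126	3.5	8.01E-15
b1943	fliK	87.3	3.7	7.25E-10
b1083	flgL	3080	3.7	5.67E-16
b1080	flgI	263	3.7	3.67E-17
b1942	fliJ	27	3.7	1.46E-05
b1939	fliG	213	3.8	3.18E-13
b1940	fliH	73	3.8	1.09E-12
b1938	fliF	645	3.8	1.44E-24
b1945	fliM	174	3.9	3.39E-18
b1078	flgG	209	3.9	2.24E-17
b1882	cheY	232	4.0	2.68E-11
b0618	citC	12	4.0	3.64E-07
b1922	fliA	3038	4.0	8.52E-18
b1074	flgC	130	4.1	1.73E-19
b1887	cheW	345	4.1	1.74E-16
b1944	fliL	46	4.1	2.57E-11
b1079	flgH	115	4.2	1.32E-16
b1925	fliS	134	4.2	4.36E-07
b4355	tsr	2250	4.2	2.59E-21
b1923	fliC	18478	4.2	3.74E-19
b1073	flgB	268	4.3	2.75E-20
b1077	flgF	532	4.3	2.31E-23
b1881	cheZ	381	4.3	1.19E-26
b1082	flgK	1771	4.3	1.75E-21
b1924	fliD	623	4.3	1.63E-16
b1947	fliO	68	4.4	7.05E-16
b0616	citE	9	4.4	7.69E-07
b1884	cheR	158	4.4	1.17E-11
b1075	flgD	400	4.5	1.13E-21
b1883	cheB	415	4.5	1.04E-20
b1921	fliZ	155	4.6	7.56E-15
b1076	flgE	677	4.6	1.14E-22
b1890	motA	267	4.6	4.60E-21
b1885	tap	1642	4.6	9.03E-23
b1888	cheA	679	4.8	1.33E-27
b1889	motB	410	4.8	5.67E-26
b1886	tar	1507	4.9	7.76E-31
b1926	fliT	21	5.3	0.000596
b0602	ybdN	36	5.5	1.86E-22
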