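locus_tag	gene	base_mean	log2fc	pvalue
b2724	hycB	29.3	-9.0	NA
b1557	cspB	48.8	-8.3	NA
b1937	fliE	66.8	7.7	NA
b0990	cspG	10.2	-7.6	NA
b2727	hypB	53.6	-7.5	NA
b2921	ygfI	21.6	-7.3	NA
b1922	fliA	3038.3	7.2	NA
b3556	cspA	247.8	-7.2	NA
b0572	cusC	1017.0	7.1	NA
b2720	hycF	37.7	-7.1	NA
b4335	yjiM	228.8	-6.9	NA
b1904	yecR	6.0	6.6	NA
b1938	fliF	645.3	6.5	NA
b1939	fliG	213.0	6.5	NA
b2721	hycE	154.6	-6.4	NA
b1729	tcyP	654.8	6.3	NA
b4037	malM	110.6	-6.2	NA
b1409	ynbB	2.4	-6.1	NA
b1674	ydhY	80.9	-6.1	NA
b2728	hypC	5.7	-6.1	NA
b1072	flgA	225.3	6.0	NA
b1886	tar	1507.2	6.0	NA
b1258	yciF	27.2	6.0	NA
b1566	flxA	402.2	6.0	NA
b1887	cheW	345.4	6.0	NA
b2378	lpxP	422.4	-5.9	NA
b1073	flgB	267.6	5.9	NA
b1375	ynaE	4.5	-5.9	NA
b1923	fliC	18478.4	5.8	NA
b1880	flhB	118.3	5.8	NA
b1942	fliJ	27.2	5.8	NA
b2971	yghG	3.4	5.8	NA
b4380	yjjI	128.5	-5.7	NA
b4034	malE	402.0	-5.7	NA
b2997	hybO	245.6	-5.7	NA
b1241	adhE	8441.5	-5.7	NA
b1925	fliS	134.0	5.6	NA
b1587	ynfE	250.8	-5.6	NA
b1083	flgL	23080.4	5.6	NA
b1552	cspI	6.3	-5.6	NA
b3370	frlA	2.1	-5.5	NA
b1589	ynfG	87.0	-5.5	NA
b1890	motA	267.0	5.4	NA
b1940	fliH	73.1	5.4	NA
b0903	pflB	23055.8	-5.4	NA
b4355	tsr	2250.0	5.4	NA
b0849	grxA	18.0	5.4	NA
b2995	hybB	157.1	-5.4	NA
b2723	hycC	118.9	-5.4	NA
b0894	dmsA	454.5	-5.4	NA
b2722	hycD	50.9	-5.4	NA
b1944	fliL	46.2	5.4	NA
b4334	yjiL	50.6	-5.3	NA
b1946	fliN	30.4	5.3	NA
b4036	lamB	191.8	-5.3	NA
b1757	ynjE	335.9	-5.3	NA
b1531	marA	33.0	5.3	NA
b2021	hisC	960.3	-5.3	NA
b1751	ydjY	133.1	-5.2	NA
b1926	fliT	21.2	5.2	NA
b4307	yjhQ	2.1	-5.2	NA
b2024	hisA	608.7	-5.2	NA
b1889	motB	409.8	5.2	NA
b4154	frdA	2376.0	-5.2	NA
b1112	bhsA	3.5	5.2	NA
b0621	dcuC	120.9	-5.1	NA
b1878	flhE	27.4	5.1	NA
b2020	hisD	1390.9	-5.1	NA
b1945	fliM	174.1	5.1	NA
b1885	tap	1641.7	5.0	NA
b2022	hisB	950.7	-5.0	NA
b0297	eaeH	1.9	-5.0	NA
b3476	nikA	126.7	-5.0	NA
b1080	flgI	263.1	5.0	NA
b1742	ves	111.3	4.9	NA
b1200	dhaK	127.4	-1.4	NA
b3634	coaD	40.9	2.6	NA
b2025	hisF	1087.6	-4.9	NA
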