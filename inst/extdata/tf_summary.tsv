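tf	renamed	n_degs	sites_chip	sites_predicted	predicted_role
ybdO	citR	86	2	1	citrate utilization, flagella biosynthesis
ygfI	dhfA	1402	2	9	dihydroxyacetone, glycerol or threonine utilization
yiaU	lpsR	674	9	5	membrane modification, LPS biosynthesis
ycaN	NA	702	6	2	unknown
ybhD	NA	238	1	2	L-malate utilization related
ybeF	NA	67	3	0	flagella biosynthesis, putative citrate utilization
yneJ	ptrR	121	9	2	putrescine utilization related
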