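pre_mirna	n_printed	site	distance_pre3
pre-miRNA-27a	6	aagccaatccc	2698
pre-miRNA-27a	6	ctcccaatgcg	1657
pre-miRNA-27a	6	aacattggtgt	3190
pre-miRNA-27a	6	ttgattggcct	1981
pre-miRNA-27a	6	ccgattggccc	2663
pre-miRNA-27a	6	gagccaatggt	4899
pre-miRNA-34a	6	tcaccaattgc	793
pre-miRNA-34a	6	gtgccaatatc	3219
pre-miRNA-34a	6	cccattggtgt	963
pre-miRNA-34a	6	cagccaatgcc	3694
pre-miRNA-34a	6	gggccaatga	1709
pre-miRNA-34a	6	ggaattggacc	1321
pre-miRNA-183	4	tgtccaatggt	2470
pre-miRNA-183	4	aggccaatgtt	769
pre-miRNA-183	4	gtgccaatatg	197
pre-miRNA-183	4	cccccaataaa	1565
pre-miRNA-31	9	tgtccaataac	2105
pre-miRNA-31	9	gtcattggatc	669
pre-miRNA-31	9	tccattggctc	2888
pre-miRNA-31	9	cacattggcct	163
pre-miRNA-31	9	tttattgggaa	705
pre-miRNA-31	9	aacattggtgc	352
pre-miRNA-31	9	gttattggctt	3706
pre-miRNA-31	9	tcaattggcca	1714
pre-miRNA-31	9	taaattggggg	3307
pre-miRNA-191	3	Aggattggcga	157
pre-miRNA-191	3	Tttattgggca	1223
pre-miRNA-191	3	ggcattggccc	3152
pre-mir-148a	5	tgaccaattcc	131
pre-mir-148a	5	aaaattggcgc	4593
pre-mir-148a	5	tgcccaattgg	3615
pre-mir-148a	5	gagattggcag	4217
pre-mir-148a	5	ccaattggtta	3618
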