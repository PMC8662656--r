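##fileformat=VCFv4.2
##source=bathypop
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10	s11	s12	s13	s14	s15	s16	s17	s18	s19	s20
scaffold_A	101	.	A	G	.	PASS	.	GT:DP:GQ	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/1:50:99	0/1:50:99	0/1:50:99	0/1:50:99	1/1:50:99
scaffold_A	151	.	A	G	.	PASS	.	GT:DP:GQ	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/1:50:99	0/1:50:99	0/1:50:99	0/1:50:99	1/1:50:99
scaffold_A	201	.	A	G	.	PASS	.	GT:DP:GQ	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/1:50:99	0/1:50:99	0/1:50:99	0/1:50:99	1/1:50:99
scaffold_A	251	.	A	G	.	PASS	.	GT:DP:GQ	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/1:50:99	0/1:50:99	0/1:50:99	0/1:50:99	1/1:50:99
scaffold_A	301	.	A	G	.	PASS	.	GT:DP:GQ	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/1:50:99	0/1:50:99	0/1:50:99	0/1:50:99	1/1:50:99
scaffold_A	351	.	A	G	.	PASS	.	GT:DP:GQ	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/1:50:99	0/1:50:99	0/1:50:99	0/1:50:99	1/1:50:99
scaffold_A	401	.	A	G	.	PASS	.	GT:DP:GQ	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/1:50:99	0/1:50:99	0/1:50:99	0/1:50:99	1/1:50:99
scaffold_A	451	.	A	G	.	PASS	.	GT:DP:GQ	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/1:50:99	0/1:50:99	0/1:50:99	0/1:50:99	1/1:50:99
scaffold_A	501	.	A	G	.	PASS	.	GT:DP:GQ	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/1:50:99	0/1:50:99	0/1:50:99	0/1:50:99	1/1:50:99
scaffold_A	551	.	A	G	.	PASS	.	GT:DP:GQ	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/1:50:99	0/1:50:99	0/1:50:99	0/1:50:99	1/1:50:99
scaffold_B	101	.	A	G	.	PASS	.	GT:DP:GQ	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/1:50:99	0/1:50:99	0/1:50:99	0/1:50:99	1/1:50:99
scaffold_C	101	.	A	G,T	.	PASS	.	GT:DP:GQ	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/0:50:99	0/1:50:99	0/1:50:99	0/1:50:99	0/1:50:99	1/1:50:99
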