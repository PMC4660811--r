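# Amplicon definition fixture: 48 bisulfite PCR target regions (multiplex panel:
# cancer-associated promoters, imprinted loci, repetitive elements, mitochondrial
# sequence, and two no-CpG control amplicons).
# Coordinates are hg38, 1-based fully-closed (UCSC style): read with
# coordinate_style = "ucsc". Columns: chrom, start, end, name, fwd_primer_len,
# rev_primer_len. Primer lengths are the genome-annealing portions (sequencing
# adapters excluded).
# Rows marked by name in the list below carry PLACEHOLDER spans (and chrUn where no
# chromosome is public): the public primer table gives no coordinates for them, and
# the foxe3_1 row is itself a documented placeholder for a panel member whose table
# row is not publicly recoverable. Placeholder spans are 150 bp windows spaced 10 kb
# apart from position 1,000,001 and carry no genomic meaning.
# Placeholder rows: AluSx_1, AluSx_2, L1ME_ORF2_1, L1ME_ORF2_2, foxe3_1, foxe3_2, foxp3_1, foxp3_2, tlx3_1, tlx3_2, uniq_noCG_1, uniq_noCG_2, mgmt_1, mgmt_2, mito_1, mito_2
chr4	154710460	154710544	mandatory01	26	23
chr1	110052409	110052486	mandatory02	23	27
chr4	7526639	7526703	mandatory03	30	27
chr2	164593225	164593299	mandatory04	26	26
chr2	9518296	9518358	mandatory05	30	28
chr17	80709100	80709203	mandatory06	25	22
chr3	142837969	142838050	mandatory07	25	28
chr7	140218100	140218192	mandatory08	27	25
chr7	26206542	26206614	mandatory09	31	27
chr7	3025554	3025664	mandatory10	24	26
chr7	138229946	138230021	mandatory11	34	28
chr2	42275714	42275789	mandatory12	23	27
chr15	100249155	100249220	mandatory13	27	27
chr4	147557821	147557938	mandatory14	29	27
chr17	75369174	75369252	mandatory15	22	25
chr7	93520244	93520332	mandatory16	31	24
chr11	2017873	2018050	h19	33	30
chr7	130131098	130131299	mest	31	28
chrX	73070975	73071183	xist	33	29
chr1	25256022	25256153	runx3	24	21
chr3	25469822	25469959	rarb	28	28
chr3	37034573	37034734	mlh1	23	30
chr3	50378200	50378398	rassf1a	29	25
chr5	112073447	112073596	apc	22	25
chr9	21974960	21975097	cdkn2a	29	26
chr9	90112783	90112938	dapk1_p1	23	30
chr9	90112991	90113144	dapk1_p2	21	21
chr9	90113588	90113759	dapk1_i1	21	32
chr11	67351064	67351273	gstp1	24	26
chr16	68771006	68771197	cdh1_snp	27	31
chr16	68771201	68771385	cdh1_3p	26	28
chr17	41277330	41277493	brca1	31	30
chrUn	1000001	1000150	AluSx_1	28	27
chrUn	1010001	1010150	AluSx_2	27	26
chrUn	1020001	1020150	L1ME_ORF2_1	30	30
chrUn	1030001	1030150	L1ME_ORF2_2	30	32
chrUn	1040001	1040150	foxe3_1	0	0
chr1	1050001	1050150	foxe3_2	23	28
chrX	1060001	1060150	foxp3_1	26	24
chrX	1070001	1070150	foxp3_2	23	26
chr5	1080001	1080150	tlx3_1	28	27
chr5	1090001	1090150	tlx3_2	24	28
chr5	1100001	1100150	uniq_noCG_1	27	33
chr5	1110001	1110150	uniq_noCG_2	28	31
chr10	1120001	1120150	mgmt_1	24	24
chr10	1130001	1130150	mgmt_2	23	28
chrM	1140001	1140150	mito_1	34	26
chrM	1150001	1150150	mito_2	29	30
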