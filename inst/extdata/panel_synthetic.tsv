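index	region	fwd_primer	rev_primer	ref_start	ref_end	insert_length
1	DLOOPB	AAAAAATCACACTGTCCGGT	GCAGCTCCGCTCAGTCATGT	171	551	381
2	ND1	GTATTTAGTCTTAGGTATGA	TGCTACACGTGGCTCCGTAG	882	1265	384
3	ND1	CTGGGATGCTGGCGACCAAT	ATCTCTAATCACAAACTAAG	1306	1674	369
4	ND1	TCCCTTCATGCGGGCTTTCA	TGTCCAGGGATCGGCAAAAG	1715	2038	324
5	ND2	CTATACATAGTTTAAGGAGG	CGAAATCTTGTCCCATCAAT	2344	2704	361
6	ND2	ACATACAACCATCTACTGCG	AGATCAGGCGTTCGGCGATC	2745	3090	346
7	COXI	CTGCAGCGATGCGGCCCTGA	GCTACACTGGTTTTGCGCAG	3482	3853	372
8	COXI	GTACGATCAGAAGAAACAGC	ATCGCAGGGCGTTGAGCCGA	3894	4275	382
9	COXII	GGCCTCAGTGCGCTGAAGCG	TGGCAGTATCGGGTAAGTAA	4570	4930	361
10	COXII	CTGGCAGCACCGCTCCTATG	TCAGGTTTTAGGGAAAAACG	4971	5281	311
11	ATP6	ACGACCTAGCTCCGCTTTAA	CAAGCGCTTCATCACTTTAA	5608	5982	375
12	ND3	AGGAACATTCTATTTGCGCG	CTTATGTAACCCCAGGAATA	6276	6632	357
13	ND4	TTAGGGTCACAGGAGGAAGA	GGCCTATTTTCATTCACTCT	6833	7195	363
14	ND4	GATCGATTTACCCACGACAT	CGTTATATGGGAGCGAGCAA	7236	7596	361
15	ND4	TTCATTACGGTACAACGTTG	GCAATTGACCTAAACTTGCG	7637	8006	370
16	ND5	AACGATATGACAGGCAGTTT	GAATGGATGTCTCGAAGCGG	8437	8781	345
17	ND5	AACCGGTGTCTATTCTTGTG	GCTTGACAGTGGTGCGCTGA	8822	9191	370
18	CYTB	ATTTGCTGTCGCGCAACCGT	GCGCGGGTCCAATGAATGGT	9598	9963	366
19	CYTB	CCCTAGATCCTTTCCCCCAG	AGCTTTGGGATAAACATGTG	10004	10355	352
20	CYTB	CTTATGCGGAATCAAGTTGG	GTGCGAATTGAAACTCAGAA	10396	10760	365
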