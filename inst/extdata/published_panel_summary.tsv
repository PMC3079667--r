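index	region	n_variants	multiallelic	transitions	transversions	indels
1	DLOOPB	21	1	11	8	2
2	ND1	15	1	13	2	0
3	ND1	5	0	5	0	0
4	ND1	8	0	8	0	0
5	ND2	13	0	13	0	0
6	ND2	7	0	5	2	0
7	COXI	12	0	12	0	0
8	COXI	12	0	11	1	0
9	COXII	7	0	7	0	0
10	COXII	7	0	7	0	0
11	ATP6	13	0	11	2	0
12	ND3	10	0	9	1	0
13	ND4	12	0	12	0	0
14	ND4	13	0	13	0	0
15	ND4	13	0	12	1	0
16	ND5	8	0	8	0	0
17	ND5	12	0	12	0	0
18	CYTB	10	0	10	0	0
19	CYTB	8	0	8	0	0
20	CYTB	12	1	9	3	0
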