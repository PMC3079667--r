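id	role	sequence
MID1	forward	CGTTTAACCT
MID2	forward	TGGCTAGTAT
MID3	forward	ACTTCAGGGT
MID4	forward	CAAGCCCTGG
MID5	forward	CGAGAAATAC
MID6	forward	GAAGATGCTT
MID7	reverse	TTCCAGCAAC
MID8	reverse	TGAAACGAGG
MID9	reverse	ACTATGCACT
MID10	reverse	CGTCGGTCTT
MID11	reverse	TCCGTAATTA
MID12	reverse	CATCGTCCAG
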