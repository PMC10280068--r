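site	ref_codon	alt_codon
1	ATT	ATC
2	TTG	CTG
3	CAG	CAA
4	CCA	CCC
5	CAC	CAT
6	GAC	GAT
7	TCG	TCA
8	AGA	ATA
9	AGA	AAA
10	GGA	GGG
11	ATA	ATT
12	TTC	TTT
13	GAG	GAA
14	GCT	ACT
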