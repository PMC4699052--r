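##fileformat=VCFv4.1
##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
1	17	.	GG	AA	.	.	SVTYPE=SUB
1	66	.	C	T	.	.	SVTYPE=SUB
1	147	.	CAGGCG	TGATGA	.	.	SVTYPE=SUB
1	231	.	GC	TG	.	.	SVTYPE=SUB
1	334	.	CAGCG	AAGGC	.	.	SVTYPE=SUB
1	373	.	C	A	.	.	SVTYPE=SUB
1	467	.	CAAGTC	ACCAAC	.	.	SVTYPE=SUB
1	1082	.	CA	C	.	.	SVTYPE=DEL
1	1096	.	T	TTGGC	.	.	SVTYPE=INS
1	1194	.	GTGTTAA	G	.	.	SVTYPE=DEL
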