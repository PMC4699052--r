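##fileformat=VCFv4.1
##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
1	66	.	C	CCGGCG	.	.	SVTYPE=INS
1	231	.	GC	TG	.	.	SVTYPE=SUB
1	334	.	CAGCG	TTCCT	.	.	SVTYPE=SUB
1	373	.	C	T	.	.	SVTYPE=SUB
1	467	.	CAAGTC	ATGATC	.	.	SVTYPE=SUB
1	1074	.	CGTGACT	TGTTACG	.	.	SVTYPE=SUB
1	1082	.	CA	C	.	.	SVTYPE=DEL
1	1106	.	GTCCT	CTCTA	.	.	SVTYPE=SUB
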