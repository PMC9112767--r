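##fileformat=VCFv4.2
##contig=<ID=chrM,length=16569>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chrM	73	.	A	G	.	.	.
chrM	263	.	A	G	.	.	.
chrM	750	.	A	G	.	.	.
chrM	1438	.	A	G	.	.	.
chrM	2706	.	A	G	.	.	.
chrM	4769	.	A	G	.	.	.
chrM	7028	.	C	T	.	.	.
chrM	8701	.	A	G	.	.	.
chrM	8860	.	A	G	.	.	.
chrM	10398	.	A	G	.	.	.
chrM	11719	.	G	A	.	.	.
chrM	12612	.	G	A	.	.	.
chrM	12705	.	C	T	.	.	.
chrM	15326	.	A	G	.	.	.
chrM	16093	.	T	C	.	.	.
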