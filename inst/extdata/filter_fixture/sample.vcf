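##fileformat=VCFv4.2
##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">
##INFO=<ID=PAF,Number=1,Type=Float,Description="Population allele frequency">
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=EFFECT,Number=1,Type=String,Description="Functional effect">
##INFO=<ID=REGION,Number=1,Type=String,Description="coding or noncoding">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr1	100	.	A	T	.	.	DP=6;PAF=0
chr1	200	.	A	T	.	.	DP=7;PAF=0
chr1	300	.	C	G	.	.	DP=7;PAF=0.002
chr1	400	.	C	G	.	.	DP=7;PAF=0.001
chr1	500	.	G	A	.	.	DP=30
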