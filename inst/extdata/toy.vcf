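##fileformat=VCFv4.2
##source=hand-built toy fixture
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3
chr1	100	.	A	G	.	PASS	.	GT	0|0	0|1	1|1
chr1	250	.	C	T	.	PASS	.	GT	0/0	./.	1/1
chr1	300	.	G	A,T	.	PASS	.	GT	0/0	0/1	0/2
chr1	420	.	T	C	.	PASS	.	GT	0|1	1|0	0|0
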