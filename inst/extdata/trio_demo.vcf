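##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	FATHER	MOTHER	PROBAND	SIBLING
1	1000	rs1	A	G	.	.	.	GT	0/1	0/1	1/1	0/0
1	2000	.	C	T	.	.	.	GT	0/1	0/1	1/1	0/1
1	3000	rs3	G	A	.	.	.	GT	0/0	0/0	1/1	0/0
1	4000	rs4	T	C	.	.	.	GT	0/1	0/1	0/1	0/0
1	5000	.	A	T	.	.	.	GT	0/1	0/0	1/1	0/0
1	6000	rs6	G	C	.	.	.	GT	0/1	0/1	1/1	1/1
1	7000	rs7	C	G	.	.	.	GT	./.	0/1	1/1	0/0
1	8000	rs8	A	C	.	.	.	GT	1/1	1/1	1/1	1/1
1	9000	rs9	T	G	.	.	.	GT	0/0	0/1	0/1	0/0
1	10000	rs10	G	T	.	.	.	GT	0/1	0/1	./.	./.
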