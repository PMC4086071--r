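chrom	pos	ref	alt	rs_id	effects	maf_kg_all	maf_kg_eur	maf_kg_asn	maf_kg_afr	maf_kg_amr	maf_esp	phenotype
1	1000	A	G	rs1	BCKDK:TX000001.1:EXON000001:exon:protein_coding:missense_variant:A/V:0.02:0.97	.	.	.	.	.	.	maple syrup urine disease-like
1	2000	C	T	.	TTN:TX000002.1:EXON000002:exon:protein_coding:synonymous_variant:.:.:.	0.12	0.10	0.15	0.09	0.11	0.13	.
1	3000	G	A	rs3	GENE3:TX000003.1:EXON000003:exon:protein_coding:missense_variant:G/D:0.40:0.10	0.004	0.003	0.006	0.002	0.005	0.004	.
1	4000	T	C	rs4	GENE4:TX000004.1:INTRON000004:intron:protein_coding:intron_variant:.:.:.	0.30	0.28	0.33	0.25	0.31	0.29	.
1	5000	A	T	.	GENE5:TX000005.1:EXON000005:exon:protein_coding:stop_gained:.:.:.	.	.	.	.	.	.	.
1	6000	G	C	rs6	GENE6:TX000006.1:EXON000006:exon:protein_coding:missense_variant:R/Q:0.50:0.20,GENE6:TX000006.2:UTR000006:three_prime_UTR:protein_coding:3_prime_UTR_variant:.:.:.	0.02	0.02	0.03	0.01	0.02	0.02	.
1	7000	C	G	rs7	GENE7:TX000007.1:EXON000007:exon:protein_coding:missense_variant:L/P:0.01:0.95	0.001	0.001	0.002	0.001	0.001	.	.
1	8000	A	C	rs8	GENE8:TX000008.1:EXON000008:exon:protein_coding:synonymous_variant:.:.:.	0.45	0.44	0.46	0.40	0.47	0.43	.
1	9000	T	G	rs9	GENE9:TX000009.1:SPLICE000009:splice_region:protein_coding:splice_region_variant:.:.:.	0.05	0.04	0.06	0.05	0.05	0.05	.
1	10000	G	T	rs10	GENE10:TX000010.1:EXON000010:exon:protein_coding:stop_lost:*/Y:.:.	.	.	.	.	.	.	.
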