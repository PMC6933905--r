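chrom	pos	id	ref	alt	A	C	G	T	af	cov	genotype
chr1	131	snp001	A	G	5	0	3	0	0.3750	8	./.
chr2	181	snp002	G	T	0	0	8	3	0.2727	11	0/1
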