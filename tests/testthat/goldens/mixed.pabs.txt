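chrom	pos	ref	A	C	G	T	af	cov	A_fwd	C_fwd	G_fwd	T_fwd	A_sb	C_sb	G_sb	T_sb
chr1	131	A	5	0	3	0	0.3750	8	3	0	2	0	0.6000	NA	0.6667	NA
chr2	161	G	0	1	5	0	0.1667	6	0	1	2	0	NA	1.0000	0.4000	NA
chr2	181	G	0	0	8	3	0.2727	11	0	0	4	2	NA	NA	0.5000	0.6667
chr2	185	C	0	9	0	1	0.1000	10	0	5	0	0	NA	0.5556	NA	0.0000
chr2	186	G	1	0	6	0	0.1429	7	0	0	4	0	0.0000	NA	0.6667	NA
chr2	192	T	0	0	1	10	0.0909	11	0	0	1	4	NA	NA	1.0000	0.4000
chr2	196	T	0	1	0	10	0.0909	11	0	0	0	4	NA	0.0000	NA	0.4000
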