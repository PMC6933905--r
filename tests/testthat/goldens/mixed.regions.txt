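chrom	start	end	sub_start	sub_end	mean_cov	sub_mean_cov	gc_content
chr1	101	160	131	160	9.8667	12.6667	0.4167
chr1	141	200	141	170	8.9667	11.7000	0.5500
chr2	151	230	183	222	8.2875	9.4500	0.4625
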