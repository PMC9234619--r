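snp_id	chrom	pos	region	minor_allele	major_allele	maf	p_value	pve
LC47339815	18	47339815	intergenic	G	A	0.11	5.62e-10	1.04
LC57373210	16	57373210	intron	A	G	0.12	8.75e-10	0.79
LC5223508	3	5223508	intergenic	A	C	0.08	2.92e-09	0.37
LC35299997	16	35299997	intron	G	A	0.10	5.45e-09	0.98
LC25289967	14	25289967	intergenic	G	A	0.17	6.33e-09	0.60
LC41179727	4	41179727	intron	A	T	0.08	1.48e-08	0.89
LC40643987	12	40643987	intergenic	A	G	0.16	2.64e-08	0.34
LC70081983	12	70081983	intron	T	A	0.05	2.78e-08	0.36
LC20163442	18	20163442	intergenic	A	C	0.45	4.74e-08	0.21
LC1059454	8	1059454	intergenic	G	A	0.11	1.60e-07	0.99
LC44890630	10	44890630	intron	T	A	0.11	6.98e-07	0.53
LC60474408	2	60474408	intergenic	C	A	0.22	1.84e-06	0.51
LC2286791	8	2286791	intron	G	A	0.09	6.00e-06	0.61
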