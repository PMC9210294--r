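chrom	ssnps	total_snps	printed_ratio
1	1170	139910	0.0084
2	310	125129	0.0025
3	459	102331	0.0045
4	330	89577	0.0037
5	372	84706	0.0044
6	1581	83605	0.0189
7	378	94371	0.0040
8	258	80617	0.0032
9	1292	67157	0.0192
10	363	56681	0.0064
11	2765	88287	0.0313
12	241	87145	0.0028
genome	9519	1099516	0.0087
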