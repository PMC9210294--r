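chrom	ssnps	total_snps	printed_ratio
1	1335	163260	0.0082
2	391	146877	0.0027
3	578	120319	0.0048
4	442	110952	0.0040
5	481	103362	0.0047
6	1724	103416	0.0167
7	459	114564	0.0040
8	373	103385	0.0036
9	1410	82744	0.0170
10	572	78206	0.0073
11	3120	112719	0.0277
12	281	106381	0.0026
genome	11166	1346185	0.0083
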