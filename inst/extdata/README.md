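Reference summary counts from two published BSA-Seq benchmark studies
(rice root-knot nematode resistance; maize cms-c fertility restoration),
used as inputs for arithmetic consistency checks in the test suite:

- snp_counts_with_parents.tsv / snp_counts_bulks_only.tsv: per-chromosome
  sSNP and total-SNP counts of the rice genome scan, with the sSNP/totalSNP
  ratio as printed (4 decimal places), for the with-parents and bulks-only
  analysis modes.
- snp_set_decomposition.tsv: decomposition of each bulks-only SNP set into
  parent-heterozygous (htSNP), bulk-specific (bsSNP), and parent-shared SNPs.
- parental_genotype_counts.tsv: homozygous/heterozygous call counts in the
  rice parental SNP set.
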