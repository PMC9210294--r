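---
title: "Methods: BSA-Seq genome scans with the significant-SNP ratio"
author: "bsaseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BSA-Seq genome scans with the significant-SNP ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `bsaseqr`, the choices
made where the procedure leaves room, and what the built-in simulator does
and does not establish about real data.

## The model

A BSA-Seq experiment sequences two pools of individuals drawn from the
phenotypic tails of a segregating population. For each biallelic SNP the data
are four read counts: `AD_ref1, AD_alt1` in bulk 1 and `AD_ref2, AD_alt2` in
bulk 2. Under the no-association null, both bulks are random samples of the
population, so conditional on the per-bulk depths the ALT counts are
binomial at the population ALT frequency — 0.5 at every locus of an F2 from
inbred parents. Linkage to a selected locus shifts the two bulks' allele
frequencies in opposite directions.

Three per-SNP statistics are computed from the 2×2 table:

* the two-sided Fisher exact P-value (enumeration of the conditional
  hypergeometric distribution; outcomes no more likely than the observed one
  are summed, with the customary `1 + 1e-7` relative tolerance on the
  comparison);
* the allele frequency difference
  `ΔAF = AD_alt2/(AD_ref2+AD_alt2) − AD_alt1/(AD_ref1+AD_alt1)`;
* the G-statistic `2·Σ O·ln(O/E)` with margin-product expectations, where
  `0·ln(0/E)` is defined as 0 (the expectations are never 0 for tables with
  at least one read per bulk).

The Fisher P-value and G are invariant when REF and ALT are exchanged
simultaneously in both bulks; ΔAF flips sign. This asymmetry is the crux of
the with/without-parents contrast: the ratio and G methods work on unanchored
bulk data, while ΔAF requires every record to be oriented so that one
parent's allele always occupies the REF position (AD/GT swapping against a
chosen *reference parent*), and the package refuses to run the ΔAF method
without parental data.

Each statistic's per-chromosome series is smoothed with a Savitzky–Golay
filter over SNP index order, and SNPs whose *smoothed* P-value falls strictly
below α (default 0.01) are flagged significant (sSNPs). The window scan
aggregates SNPs into sliding windows (2 Mb advanced by 10 kb by default; a
5 Mb preset suits maize-sized genomes): the window's ratio statistic is
`sSNP count / total SNP count`, and its ΔAF and G statistics are the means of
the smoothed per-SNP values.

## Thresholds by simulation

All significance thresholds are Monte-Carlo estimates under the null,
re-using each SNP's observed per-bulk depths:

* **ΔAF band / G threshold** (per SNP): `replicates` null tables per SNP
  (default 10,000); the two-sided 99% band of simulated ΔAF and the 99.5th
  percentile of simulated G. The per-chromosome threshold series are smoothed
  with the same Savitzky–Golay settings as the observed tracks, and windows
  average the per-SNP thresholds of their members.
* **Ratio, genome-wide**: per replicate, as many SNPs as an average window
  holds are resampled (with replacement) from the whole dataset, simulated
  under the null, and tested; sSNPs inside the simulation are called at the
  looser `alpha_sim = 0.10` on the raw simulated P-values, which inflates the
  simulated ratios and makes the threshold conservative. The threshold is the
  99.5th percentile of the replicate ratios.
* **Ratio, per window**: identical but without resampling — the window's own
  SNPs are simulated. Computing this for every window would be prohibitive,
  so it is used only to *verify* candidate peaks found with the genome-wide
  threshold (two-stage testing). Windows with few SNPs receive markedly
  higher thresholds, which the verification stage needs no special casing
  for.

Percentiles are nearest-rank order statistics (no interpolation), so every
threshold is an attainable value of the simulated statistic. Below 100
replicates the functions warn that percentile estimates are unstable. A
single seed drives a run; threshold operations re-seed deterministically from
`null_model(seed =)` with small fixed offsets so each estimate is also
reproducible in isolation.

## SNP filtering

Records pass a fixed-order rule chain, each record attributed to the first
rule it fails (so removal reports are deterministic): organellar/unplaced
chromosomes; missing values in any used field; the two-ALT renormalization
(REF replaced by the first ALT when no sample shows a REF read, the leading
AD entry dropped) applied *before* the genotype-agreement checks; removal of
monomorphic zero-REF records, of records with ≥3 ALT alleles, and of two-ALT
records with REF reads; genotype/REF-ALT agreement; genotype/AD consistency;
the bulk GQ floor (default 20); the depth cap (default 6× the average
coverage, user-supplied or estimated as the per-bulk median depth); and, with
parents, removal of records heterozygous in any parent. The genotype/AD
consistency rule is read strictly: a homozygous call must show reads only for
the called allele (and at least one), a heterozygous call must show reads for
both — this also guarantees every surviving record has at least one read per
sample, which the exact test requires. Parents are filtered with the same
hygiene rules, but their GQ floor (the same 20; the bulk value is reused for
symmetry) is applied only *after* the bulk/parent intersection, which matches
the documented order of the original workflow. Multi-sample inputs may carry
unmapped columns; they are ignored.

## Sliding windows and peaks

Windows are 1-based half-open `[start, start + size)` intervals anchored at
position 1, advancing by `step` until the chromosome's last SNP is covered;
interior SNP-free windows are kept (ratio `NA`), trailing ones dropped.
Candidate regions are maximal runs of consecutive windows above threshold
(outside the band, for ΔAF), and each run's peak is its extreme window. Two
conventions deserve note:

* **Ties.** Around a strong locus at high depth, *every* SNP can be
  significant over tens of cM, so the ratio track saturates at 1.0 across
  long stretches. The peak is therefore taken as the *middle* of the run's
  tied-maximum stretch rather than its first window, which would otherwise
  bias peaks toward the left edge of the saturated region.
* **Truncated end windows.** Windows that extend past the chromosome's last
  SNP can hold a handful of SNPs whose ratio is 0 or 1 by accident; they
  remain part of runs but are never reported as the peak window (a run with
  no fully covered window yields no peak). Peak positions are reported at the
  window start by default (midpoint optional).

Ratio peaks are then verified against their own window-specific simulated
threshold; `verified` peaks are those strictly above it.

## The simulator

`sim_design()`/`simulate_bsaseq()` generate an F2 from inbred parents: two
recombining gametes per individual per chromosome, Poisson crossover counts
at the configured map density (4 cM/Mb by default, a rice-like genome-wide
average; crossover positions uniform, no interference — a Haldane map), so
marginal genotypes segregate 1:2:1 with physically linked loci. Phenotypes
are the sum over QTLs of `a·(g−1) + h·a·[g=1]` (`h = 0` incomplete dominant,
`h = 1` fully dominant) plus Gaussian noise; bulks are the phenotypic tails
with random tie-breaking. Sequencing draws Poisson depths (default 20×, the
scale of the package's validation studies; population of 178 with bulks of
23 by default) and binomial ALT reads at each bulk's realized allele
frequency; genotypes are called naively from the reads and GQ grows with
depth. At a configurable fraction of loci (default 0.5, an unrelated
reference genome) the emitted REF allele is parent 2's allele, so the
orientation is random with respect to parent of origin until AD/GT swapping
re-anchors it — this is what makes the unswapped ΔAF track lose its peaks.

Contamination is injected at extra loci. *htSNPs* (heterozygous in one
parent) are modeled as loci that still segregate through the single F1 —
their bulk frequencies follow the local haplotype composition (taken from the
nearest simulated locus), so near a trait locus they are enriched like
ordinary SNPs. This matters: if htSNP frequencies were drawn trait-independent
near 0.5, interleaved contaminants would drag the smoothed P-values of whole
neighborhoods above α and peak detection in bulks-only mode would collapse —
the opposite of the observed behavior, where contamination mainly inflates
window totals and dilutes the ratio. *bsSNPs* (bulk-specific, absent from the
parental data) are artifact-like: one uniform(0, 1) underlying frequency
shared by both bulks. Populations bulked from several F1 plants, mapping
bias, InDel-specific error modes, and duplication artifacts are *not*
modeled, so passing recovery tests demonstrate internal consistency of the
method at the stated design, not robustness to every real-data pathology.

## Numerical and scale choices

* Savitzky–Golay defaults: window 51 SNPs, order 3 — wide enough to suppress
  read-sampling noise at 100 SNPs/Mb without flattening multi-Mb peaks; both
  are configurable, and the package's acceptance properties hold across
  reasonable settings. Chromosomes shorter than the window pass through
  unsmoothed; smoothed P-values are clamped into [0, 1].
* Ties at `P = α` are non-significant; `alpha` must lie strictly in (0, 1).
* Fisher P-values are memoized over duplicate tables, which makes the
  simulation thresholds tractable (millions of low-depth tables recur).
* The null ALT frequency is the theoretical population value (0.5 for an F2),
  configurable for other designs, rather than a data estimate.
* Test and validation scans run at deliberately small scale — genomes of
  6–20 Mb, 80–100 SNPs/Mb, 200–2,000 Monte-Carlo replicates, 20-seed
  replicate sets — chosen so the full suite exercises every stage end to end;
  production scans should keep the 10,000-replicate default.

## Known limitations

At 20× depth with perfect phenotypic selection, every SNP within roughly
40 cM of a strong locus is significant, so the ratio track saturates and
localization is linkage-limited: the peak window identifies the saturated
region's center, not a fine-mapped interval. Lower depth, weaker loci, or
noisy phenotypes sharpen the track but weaken detection. The sSNP/totalSNP
ratio inherits the discreteness of Fisher's exact test: at depths below ~5
reads per bulk no SNP can reach α = 0.01, so deserts of shallow coverage
depress the ratio regardless of linkage. InDels, when present in the input,
are treated exactly like SNPs.
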