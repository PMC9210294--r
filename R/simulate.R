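#' Design of a synthetic BSA-Seq experiment
#'
#' Describes the cross, genome, trait architecture, and sequencing layout
#' used by the simulator. Defaults emulate a rice-scale F2 BSA-Seq study:
#' a population of 178 plants, bulks of 23 plants per phenotypic tail,
#' 20x mean bulk depth, and a single incomplete-dominant locus.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param snp_per_mb SNP density (segregating SNPs per Mb).
#' @param pop_type population type; only `"F2"` is implemented (null ALT
#'   frequency 0.5 per locus).
#' @param pop_size number of F2 individuals.
#' @param bulk_size individuals per phenotypic-tail bulk (at most half the
#'   population).
#' @param qtl data frame of trait loci: columns `chrom`, `pos`, `effect`
#'   (additive effect a; genotype values are -a, a*dominance, +a for 0/1/2
#'   ALT copies), and `dominance` (0 = incomplete dominant/additive,
#'   1 = fully dominant ALT).
#' @param noise_sd standard deviation of the Gaussian environmental noise
#'   added to the genetic value.
#' @param mean_depth mean per-SNP sequencing depth of each bulk (X-fold,
#'   Poisson-distributed per SNP).
#' @param parent_het_rate fraction of extra SNP loci heterozygous in a
#'   parental line (htSNP contamination), relative to the segregating SNP
#'   count.
#' @param bssnp_rate fraction of extra bulk-specific SNP loci (bsSNP
#'   contamination) absent from the parental data; their underlying allele
#'   frequency is uniform(0, 1), shared by both bulks.
#' @param cm_per_mb recombination map density (centimorgan per Mb).
#' @param ref_flip_rate fraction of loci at which the reference genome
#'   carries parent 2's allele, so the emitted REF/ALT orientation must be
#'   re-anchored by AD/GT swapping; 0.5 models an unrelated reference.
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(chrom_lengths = c(Chr01 = 3e7, Chr02 = 3e7),
                       snp_per_mb = 100, pop_type = "F2", pop_size = 178L,
                       bulk_size = 23L,
                       qtl = data.frame(chrom = "Chr01", pos = 1.5e7,
                                        effect = 1, dominance = 0),
                       noise_sd = 0, mean_depth = 20,
                       parent_het_rate = 0, bssnp_rate = 0,
                       cm_per_mb = 4, ref_flip_rate = 0.5) {
  pop_type <- match.arg(pop_type, "F2")
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0),
            !is.null(names(chrom_lengths)), snp_per_mb > 0,
            pop_size >= 2, bulk_size >= 1, bulk_size <= pop_size / 2,
            noise_sd >= 0, mean_depth > 0,
            parent_het_rate >= 0, parent_het_rate <= 1,
            bssnp_rate >= 0, bssnp_rate <= 1,
            cm_per_mb >= 0, ref_flip_rate >= 0, ref_flip_rate <= 1)
  if (nrow(qtl)) {
    stopifnot(all(qtl$chrom %in% names(chrom_lengths)),
              all(qtl$pos >= 1 & qtl$pos <= chrom_lengths[qtl$chrom]),
              all(is.finite(qtl$effect)),
              all(qtl$dominance >= 0 & qtl$dominance <= 1))
  }
  structure(list(chrom_lengths = chrom_lengths, snp_per_mb = snp_per_mb,
                 pop_type = pop_type, pop_size = as.integer(pop_size),
                 bulk_size = as.integer(bulk_size), qtl = qtl,
                 noise_sd = noise_sd, mean_depth = mean_depth,
                 parent_het_rate = parent_het_rate, bssnp_rate = bssnp_rate,
                 cm_per_mb = cm_per_mb, ref_flip_rate = ref_flip_rate),
            class = "sim_design")
}

# One recombinant gamete per call: ALT(parent-2)-haplotype indicator at each
# locus, built from a Poisson number of crossovers placed uniformly.
.gamete <- function(pos, len, cm_per_mb) {
  n_co <- stats::rpois(1L, len / 1e6 * cm_per_mb / 100)
  start <- stats::rbinom(1L, 1L, 0.5)
  if (n_co == 0L) return(rep.int(start, length(pos)))
  breaks <- sort(stats::runif(n_co, 0, len))
  (start + findInterval(pos, breaks)) %% 2L
}

#' Simulate an F2 population
#'
#' Generates SNP positions along each chromosome at the design's density
#' (plus the exact QTL positions) and, for each individual, two recombining
#' gametes per chromosome: crossover counts are Poisson with the design's map
#' density, crossover positions uniform, and chromosomes independent. Each
#' locus therefore segregates 1:2:1 marginally, with physical linkage between
#' nearby loci. Genotypes are ALT-allele dosages (0/1/2), where ALT is the
#' parent-2 allele.
#'
#' @param design a [sim_design()].
#' @return a list of class `bsa_population`: `map` (data frame `chrom`,
#'   `pos`, `is_qtl`) and `geno` (integer matrix, individuals x loci).
#' @export
simulate_population <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  maps <- list()
  for (chrom in names(design$chrom_lengths)) {
    len <- design$chrom_lengths[[chrom]]
    m <- max(1L, round(len / 1e6 * design$snp_per_mb))
    pos <- sort(sample.int(len, m))
    qpos <- design$qtl$pos[design$qtl$chrom == chrom]
    pos <- sort(unique(c(pos, qpos)))
    maps[[chrom]] <- data.frame(chrom = chrom, pos = as.integer(pos),
                                is_qtl = pos %in% qpos,
                                stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  n <- design$pop_size
  geno <- matrix(0L, n, nrow(map))
  off <- 0L
  for (chrom in names(design$chrom_lengths)) {
    pos <- maps[[chrom]]$pos
    len <- design$chrom_lengths[[chrom]]
    m <- length(pos)
    for (i in seq_len(n)) {
      geno[i, off + seq_len(m)] <- .gamete(pos, len, design$cm_per_mb) +
        .gamete(pos, len, design$cm_per_mb)
    }
    off <- off + m
  }
  structure(list(map = map, geno = geno), class = "bsa_population")
}

#' Phenotypes from QTL genotypes
#'
#' Genetic value of individual i is the sum over QTLs of
#' `effect * (g - 1) + dominance * effect * (g == 1)` where g is the ALT
#' dosage, plus Gaussian noise with the design's `noise_sd`.
#'
#' @param pop a `bsa_population`.
#' @param design the [sim_design()] used to create it.
#' @return numeric phenotype vector.
#' @export
sim_phenotypes <- function(pop, design) {
  n <- nrow(pop$geno)
  value <- numeric(n)
  for (k in seq_len(nrow(design$qtl))) {
    j <- which(pop$map$chrom == design$qtl$chrom[k] &
                 pop$map$pos == design$qtl$pos[k])
    stopifnot(length(j) == 1L)
    g <- pop$geno[, j]
    a <- design$qtl$effect[k]
    value <- value + a * (g - 1) + design$qtl$dominance[k] * a * (g == 1)
  }
  value + stats::rnorm(n, 0, design$noise_sd)
}

#' Select the phenotypic-tail bulks
#'
#' Bulk 1 (high) takes the `bulk_size` individuals with the largest
#' phenotypes, bulk 2 (low) those with the smallest; ties are broken at
#' random, so within a phenotype class membership is a random sample.
#'
#' @param phenotypes numeric phenotype vector.
#' @param bulk_size individuals per bulk.
#' @return list of class `bsa_bulks` with integer index vectors `high`,
#'   `low`.
#' @export
select_bulks <- function(phenotypes, bulk_size) {
  n <- length(phenotypes)
  if (2 * bulk_size > n) stop("bulk size exceeds half the population")
  tie <- stats::runif(n)
  ord <- order(phenotypes, tie, decreasing = TRUE)
  structure(list(high = ord[seq_len(bulk_size)],
                 low = rev(ord)[seq_len(bulk_size)]),
            class = "bsa_bulks")
}

#' ALT allele frequency of a set of individuals
#'
#' @param pop a `bsa_population`.
#' @param idx individual indices (e.g. a bulk).
#' @return numeric vector of per-locus ALT frequencies in \[0, 1\].
#' @export
bulk_allele_freq <- function(pop, idx) {
  colMeans(pop$geno[idx, , drop = FALSE]) / 2
}

.random_bases <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  cbind(ref = unname(ref), alt = unname(alt))
}

# Naive genotype call from a biallelic read pair (REF-first orientation).
.call_gt <- function(ref_reads, alt_reads, ref, alt) {
  ifelse(ref_reads + alt_reads == 0L, NA_character_,
         ifelse(alt_reads == 0L, paste(ref, ref, sep = "/"),
                ifelse(ref_reads == 0L, paste(alt, alt, sep = "/"),
                       paste(ref, alt, sep = "/"))))
}

.gq_from_depth <- function(depth) pmin(99L, 20L + 3L * as.integer(depth))

#' Sequence the bulks (and parents) of a simulated cross
#'
#' Turns bulk compositions into a BSA-Seq SNP table in the VariantsToTable
#' dialect. For every segregating locus: per-bulk total depth is Poisson at
#' the design's mean depth; ALT reads are binomial at the bulk's true allele
#' frequency; genotypes are called naively from the reads, and GQ grows with
#' depth (>= 20 whenever any read was seen). At a fraction `ref_flip_rate` of
#' loci the emitted REF allele is parent 2's allele, so downstream analysis
#' must re-anchor orientation by AD/GT swapping. Contamination is injected at
#' extra loci: htSNPs at `parent_het_rate` (heterozygous in one parent, but
#' still segregating through the single F1, so their bulk frequencies follow
#' the local haplotype composition - near a trait locus they are enriched
#' like ordinary SNPs), and bulk-only bsSNPs at `bssnp_rate` (artifact-like:
#' one uniform(0, 1) underlying frequency shared by both bulks, absent from
#' the parental table). Zero-depth calls are emitted as missing, for the
#' missing-value filter to remove.
#'
#' @param pop a `bsa_population`.
#' @param bulks a `bsa_bulks` selection.
#' @param design the [sim_design()].
#' @param parents also emit the parental SNP table (default TRUE).
#' @return list: `bulks` (a `snp_tbl` with bulk1/bulk2 columns), `parents`
#'   (a `snp_tbl` with parent1/parent2 columns, or NULL), and `truth` (per
#'   locus: class `shared`/`htSNP`/`bsSNP`, true parent-2-allele bulk
#'   frequencies, orientation flip flag, QTL flag).
#' @export
sequence_bulks <- function(pop, bulks, design, parents = TRUE) {
  map <- pop$map
  m <- nrow(map)
  f_high <- bulk_allele_freq(pop, bulks$high)
  f_low <- bulk_allele_freq(pop, bulks$low)

  # contamination loci
  n_ht <- round(design$parent_het_rate * m)
  n_bs <- round(design$bssnp_rate * m)
  extra <- function(n_extra) {
    if (!n_extra) return(map[0, ])
    lens <- design$chrom_lengths
    ch <- sample(names(lens), n_extra, replace = TRUE,
                 prob = lens / sum(lens))
    data.frame(chrom = ch,
               pos = vapply(ch, function(c0) sample.int(lens[[c0]], 1L),
                            integer(1)),
               is_qtl = FALSE, stringsAsFactors = FALSE)
  }
  # htSNPs segregate through the (single) F1 like any other locus, so their
  # bulk frequencies track the local haplotype composition: take the nearest
  # simulated locus's realized frequencies
  ht_map <- extra(n_ht)
  nearest <- function(chrom, pos) {
    vapply(seq_along(pos), function(i) {
      j <- which(map$chrom == chrom[i])
      j[pmax(1L, findInterval(pos[i], map$pos[j]))]
    }, integer(1))
  }
  ht_near <- if (n_ht) nearest(ht_map$chrom, ht_map$pos) else integer(0)
  ht_high <- f_high[ht_near]
  ht_low <- f_low[ht_near]
  # bsSNPs are artifact-like: one underlying frequency per locus, shared by
  # the bulks, drawn uniform(0, 1)
  bs_map <- extra(n_bs)
  draws <- 2L * design$bulk_size
  bs_u <- stats::runif(n_bs)
  bs_high <- stats::rbinom(n_bs, draws, bs_u) / draws
  bs_low <- stats::rbinom(n_bs, draws, bs_u) / draws

  all_map <- rbind(map, ht_map, bs_map)
  cls <- rep(c("shared", "htSNP", "bsSNP"), c(m, n_ht, n_bs))
  fh <- c(f_high, ht_high, bs_high)
  fl <- c(f_low, ht_low, bs_low)
  M <- nrow(all_map)
  flip <- stats::rbinom(M, 1L, design$ref_flip_rate) == 1L
  bases <- .random_bases(M)
  ref <- bases[, "ref"]; alt <- bases[, "alt"]
  # emitted ALT frequency: parent-2 allele unless the orientation is flipped
  eh <- ifelse(flip, 1 - fh, fh)
  el <- ifelse(flip, 1 - fl, fl)

  bulk_cols <- function(f_emit) {
    depth <- stats::rpois(M, design$mean_depth)
    a <- stats::rbinom(M, depth, f_emit)
    r <- depth - a
    list(GT = .call_gt(r, a, ref, alt),
         AD = paste(r, a, sep = ","),
         GQ = ifelse(depth == 0L, 0L, .gq_from_depth(depth)))
  }
  b1 <- bulk_cols(eh)
  b2 <- bulk_cols(el)
  qual <- round(stats::runif(M, 100, 2000), 2)
  bulks_tbl <- data.frame(CHROM = all_map$chrom, POS = all_map$pos,
                          QUAL = qual, REF = ref, ALT = alt,
                          bulk1.GT = b1$GT, bulk1.AD = b1$AD, bulk1.GQ = b1$GQ,
                          bulk2.GT = b2$GT, bulk2.AD = b2$AD, bulk2.GQ = b2$GQ,
                          stringsAsFactors = FALSE)
  truth <- data.frame(CHROM = all_map$chrom, POS = all_map$pos,
                      class = cls, is_qtl = all_map$is_qtl,
                      true_freq_high = fh, true_freq_low = fl,
                      flipped = flip, stringsAsFactors = FALSE)
  ord <- order(match(bulks_tbl$CHROM, names(design$chrom_lengths)),
               bulks_tbl$POS)
  bulks_tbl <- bulks_tbl[ord, ]
  truth <- truth[ord, ]
  rownames(bulks_tbl) <- rownames(truth) <- NULL
  broles <- sample_roles("bulk1", "bulk2")
  bulks_tbl <- .as_snp_tbl(bulks_tbl, broles)

  parents_tbl <- NULL
  if (parents) {
    in_parents <- truth$class %in% c("shared", "htSNP")
    pm <- sum(in_parents)
    pref <- bulks_tbl$REF[in_parents]
    palt <- bulks_tbl$ALT[in_parents]
    pflip <- truth$flipped[in_parents]
    is_ht <- truth$class[in_parents] == "htSNP"
    het_in_p1 <- is_ht & stats::rbinom(pm, 1L, 0.5) == 1L
    het_in_p2 <- is_ht & !het_in_p1
    parent_cols <- function(hom_alt, het) {
      depth <- pmax(1L, stats::rpois(pm, design$mean_depth))
      depth <- ifelse(het, pmax(depth, 2L), depth)
      # heterozygous calls must show both alleles (one read reserved per allele)
      a <- ifelse(het, 1L + stats::rbinom(pm, pmax(depth - 2L, 0L), 0.5),
                  ifelse(hom_alt, depth, 0L))
      r <- depth - a
      list(GT = ifelse(het, paste(pref, palt, sep = "/"),
                       .call_gt(r, a, pref, palt)),
           AD = paste(r, a, sep = ","),
           GQ = .gq_from_depth(depth))
    }
    # parent1 carries the dosage-0 allele: hom REF unless flipped
    p1 <- parent_cols(hom_alt = pflip, het = het_in_p1)
    p2 <- parent_cols(hom_alt = !pflip, het = het_in_p2)
    parents_tbl <- data.frame(CHROM = bulks_tbl$CHROM[in_parents],
                              POS = bulks_tbl$POS[in_parents],
                              QUAL = bulks_tbl$QUAL[in_parents],
                              REF = pref, ALT = palt,
                              parent1.GT = p1$GT, parent1.AD = p1$AD,
                              parent1.GQ = p1$GQ,
                              parent2.GT = p2$GT, parent2.AD = p2$AD,
                              parent2.GQ = p2$GQ,
                              stringsAsFactors = FALSE)
    parents_tbl <- .as_snp_tbl(parents_tbl,
                               sample_roles("bulk1", "bulk2",
                                            parent1 = "parent1",
                                            parent2 = "parent2",
                                            reference_parent = "parent1"))
  }
  list(bulks = bulks_tbl, parents = parents_tbl, truth = truth)
}

#' Simulate a complete BSA-Seq experiment
#'
#' Convenience wrapper: population, phenotypes, tail bulks, and sequencing in
#' one call.
#'
#' @param design a [sim_design()].
#' @param seed optional seed for reproducibility.
#' @param parents emit parental tables too (default TRUE).
#' @return list of class `bsa_sim`: `bulks`, `parents`, `truth`,
#'   `phenotypes`, `bulk_idx`, `design`.
#' @export
simulate_bsaseq <- function(design = sim_design(), seed = NULL,
                            parents = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  pop <- simulate_population(design)
  phen <- sim_phenotypes(pop, design)
  bulks <- select_bulks(phen, design$bulk_size)
  seq <- sequence_bulks(pop, bulks, design, parents = parents)
  structure(c(seq, list(phenotypes = phen, bulk_idx = bulks,
                        design = design)),
            class = "bsa_sim")
}
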