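test_that("F2 loci segregate 1:2:1 with distance-dependent linkage", {
  set.seed(21)
  d <- sim_design(chrom_lengths = c(Chr01 = 2e7, Chr02 = 1e7), snp_per_mb = 2,
                  pop_size = 4000L, bulk_size = 500L,
                  qtl = data.frame(chrom = "Chr01", pos = 1e7, effect = 1,
                                   dominance = 0))
  pop <- simulate_population(d)
  g <- pop$geno
  n <- nrow(g)
  # marginal genotype frequencies at a few loci, within 3 binomial SEs
  for (j in c(1L, 10L, ncol(g))) {
    se <- sqrt(0.25 * 0.75 / n)
    expect_lt(abs(mean(g[, j] == 0) - 0.25), 3 * se + 1e-9)
    expect_lt(abs(mean(g[, j] == 1) - 0.50), 3 * sqrt(0.25 / n) + 1e-9)
  }
  # dosage correlation (1 - 2r for an F2) decays with distance per the
  # Haldane map, and vanishes across chromosomes
  on1 <- which(pop$map$chrom == "Chr01")
  ref <- on1[1]
  d_mb <- (pop$map$pos[on1] - pop$map$pos[on1[1]]) / 1e6
  for (k in c(5L, 20L)) {
    r_hat <- (1 - cor(g[, ref], g[, on1[k]])) / 2
    r_exp <- 0.5 * (1 - exp(-2 * d_mb[k] * d$cm_per_mb / 100))
    expect_lt(abs(r_hat - r_exp), 0.05)
  }
  r5 <- (1 - cor(g[, ref], g[, on1[5]])) / 2
  r20 <- (1 - cor(g[, ref], g[, on1[20]])) / 2
  expect_lt(r5, r20)
  across <- cor(g[, on1[1]], g[, which(pop$map$chrom == "Chr02")[1]])
  expect_lt(abs(across), 0.06)
})

test_that("zero recombination keeps whole-chromosome haplotypes intact", {
  set.seed(22)
  d <- sim_design(chrom_lengths = c(Chr01 = 1e7), snp_per_mb = 5,
                  pop_size = 50L, bulk_size = 10L, cm_per_mb = 0,
                  qtl = data.frame(chrom = "Chr01", pos = 5e6, effect = 1,
                                   dominance = 0))
  pop <- simulate_population(d)
  expect_true(all(apply(pop$geno, 1L, function(r) length(unique(r)) == 1L)))
})

test_that("perfect phenotypic selection recovers the analytic bulk frequencies", {
  set.seed(23)
  # incomplete dominant, zero noise: tails are opposite homozygotes
  d <- sim_design(chrom_lengths = c(Chr01 = 1e6), snp_per_mb = 3,
                  pop_size = 3000L, bulk_size = 600L,
                  qtl = data.frame(chrom = "Chr01", pos = 5e5, effect = 1,
                                   dominance = 0))
  pop <- simulate_population(d)
  phen <- sim_phenotypes(pop, d)
  b <- select_bulks(phen, 600L)
  j <- which(pop$map$is_qtl)
  expect_equal(unname(bulk_allele_freq(pop, b$high)[j]), 1)
  expect_equal(unname(bulk_allele_freq(pop, b$low)[j]), 0)

  # fully dominant: the dominant-phenotype class carries 2/3 ALT alleles
  d2 <- sim_design(chrom_lengths = c(Chr01 = 1e6), snp_per_mb = 3,
                   pop_size = 6000L, bulk_size = 1000L,
                   qtl = data.frame(chrom = "Chr01", pos = 5e5, effect = 1,
                                    dominance = 1))
  pop2 <- simulate_population(d2)
  phen2 <- sim_phenotypes(pop2, d2)
  dom <- which(phen2 > min(phen2))
  j2 <- which(pop2$map$is_qtl)
  f_dom <- mean(pop2$geno[dom, j2]) / 2
  expect_lt(abs(f_dom - 2 / 3), 3 * sqrt(2 / 9 / (2 * length(dom))))
  # recessive-phenotype bulk is fixed for the other allele
  rec <- which(phen2 == min(phen2))
  expect_equal(mean(pop2$geno[rec, j2]), 0)

  # no QTL: bulks are random, frequencies near 0.5 genome-wide
  d0 <- sim_design(chrom_lengths = c(Chr01 = 1e6), snp_per_mb = 20,
                   pop_size = 3000L, bulk_size = 600L,
                   qtl = data.frame(chrom = character(), pos = numeric(),
                                    effect = numeric(), dominance = numeric()))
  pop0 <- simulate_population(d0)
  b0 <- select_bulks(sim_phenotypes(pop0, d0), 600L)
  expect_lt(abs(mean(bulk_allele_freq(pop0, b0$high)) - 0.5), 0.03)

  expect_error(select_bulks(phen, 2000L), "bulk size")
})

test_that("sequenced tables carry coherent truth labels and contamination", {
  d <- sim_design(chrom_lengths = c(Chr01 = 5e6), snp_per_mb = 60,
                  qtl = data.frame(chrom = "Chr01", pos = 2.5e6, effect = 1,
                                   dominance = 0),
                  parent_het_rate = 0.1, bssnp_rate = 0.05)
  sim <- simulate_bsaseq(d, seed = 31)
  expect_equal(nrow(sim$bulks), nrow(sim$truth))
  expect_equal(sort(unique(sim$truth$class)), c("bsSNP", "htSNP", "shared"))
  n_shared <- sum(sim$truth$class == "shared")
  expect_equal(sum(sim$truth$class == "htSNP"), round(0.1 * n_shared))
  expect_equal(sum(sim$truth$class == "bsSNP"), round(0.05 * n_shared))
  # parent table lacks exactly the bsSNPs
  expect_equal(nrow(sim$parents), nrow(sim$bulks) -
                 sum(sim$truth$class == "bsSNP"))
  # diagnosed classes match the truth labels
  cls <- classify_parent_origin(sim$bulks, sim$parents)
  expect_equal(as.character(cls$parent_class), sim$truth$class)

  # null loci have balanced read fractions on average
  far <- sim$truth$class == "shared" & !sim$truth$is_qtl
  ad <- do.call(rbind, strsplit(sim$bulks$bulk1.AD[far], ","))
  alt_frac <- sum(as.integer(ad[, 2])) / sum(as.integer(ad))
  expect_lt(abs(alt_frac - 0.5), 0.05)
})

test_that("a contamination-free simulation classifies everything as shared", {
  d <- sim_design(chrom_lengths = c(Chr01 = 2e6), snp_per_mb = 30,
                  qtl = data.frame(chrom = "Chr01", pos = 1e6, effect = 1,
                                   dominance = 0))
  sim <- simulate_bsaseq(d, seed = 32)
  cls <- classify_parent_origin(sim$bulks, sim$parents)
  expect_true(all(cls$parent_class == "shared"))
})

test_that("sequencing respects the configured mean depth and flags missing calls", {
  d <- sim_design(chrom_lengths = c(Chr01 = 2e6), snp_per_mb = 100,
                  mean_depth = 2,
                  qtl = data.frame(chrom = "Chr01", pos = 1e6, effect = 1,
                                   dominance = 0))
  sim <- simulate_bsaseq(d, seed = 33)
  depths <- sapply(strsplit(sim$bulks$bulk1.AD, ","),
                   function(p) sum(as.integer(p)))
  expect_lt(abs(mean(depths) - 2), 0.3)
  zero <- depths == 0
  expect_true(any(zero))  # Poisson(2) produces zero-depth calls
  expect_true(all(is.na(sim$bulks$bulk1.GT[zero])))
  res <- filter_snps(sim$bulks, filter_config(mean_coverage = 2))
  expect_gte(res$report$removed["missing_value"], sum(zero))
})
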