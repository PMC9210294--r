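stats_tbl_from <- function(chrom, pos, is_ssnp, depth = 20L,
                           extra = NULL) {
  n <- length(pos)
  x <- data.frame(CHROM = chrom, POS = as.integer(pos), QUAL = 500,
                  REF = "A", ALT = "T",
                  bulk1.GT = "A/T",
                  bulk1.AD = paste(depth %/% 2, depth - depth %/% 2, sep = ","),
                  bulk1.GQ = 40L,
                  bulk2.GT = "A/T",
                  bulk2.AD = paste(depth %/% 2, depth - depth %/% 2, sep = ","),
                  bulk2.GQ = 40L,
                  is_ssnp = is_ssnp, stringsAsFactors = FALSE)
  if (!is.null(extra)) x <- cbind(x, extra)
  class(x) <- c("snp_tbl", "data.frame")
  attr(x, "roles") <- sample_roles("bulk1", "bulk2")
  x
}

test_that("window ratios reproduce the printed peak-window arithmetic", {
  # 1139 SNPs inside the first 2 Mb window, 675 of them significant
  set.seed(1)
  pos <- sort(sample.int(1999000L, 1139L))
  flags <- rep(FALSE, 1139L)
  flags[sample.int(1139L, 675L)] <- TRUE
  x <- stats_tbl_from("Chr11", pos, flags)
  w <- build_windows(x, window_config(2e6, 1e4))
  expect_equal(w$ssnps[1], 675L)
  expect_equal(w$total_snps[1], 1139L)
  expect_equal(round(w$ratio[1], 4), 0.5926)
})

test_that("each interior SNP falls in window_size/step consecutive windows", {
  pos <- seq(1000L, 300000L, by = 500L)
  x <- stats_tbl_from("Chr01", pos, rep(FALSE, length(pos)))
  cfg <- window_config(1e5, 1e4)
  w <- build_windows(x, cfg)
  p <- 150000L  # interior SNP
  holds <- sum(w$start <= p & p < w$end)
  expect_equal(holds, cfg$window_size / cfg$step)
  # step-wide non-overlapping windows partition the SNPs
  w1 <- build_windows(x, window_config(1e4, 1e4))
  expect_equal(sum(w1$total_snps), length(pos))
})

test_that("window ratio equals the mean of per-SNP sSNP indicators", {
  set.seed(8)
  pos <- sort(sample.int(5e5, 400))
  flags <- runif(400) < 0.3
  x <- stats_tbl_from("Chr01", pos, flags)
  w <- build_windows(x, window_config(1e5, 2.5e4))
  manual <- vapply(seq_len(nrow(w)), function(i) {
    inw <- pos >= w$start[i] & pos < w$end[i]
    if (!any(inw)) NA_real_ else mean(flags[inw])
  }, numeric(1))
  expect_equal(w$ratio, manual)
  expect_error(build_windows(stats_tbl_from("Chr01", rev(pos), flags),
                             window_config(1e5, 2.5e4)), "sorted")
})

test_that("mean SNP count per window is order-invariant arithmetic", {
  w <- data.frame(chrom = "c", start = 1, end = 2,
                  total_snps = c(4L, 6L, 8L))
  expect_equal(mean_snp_count_per_window(w), 6)
  expect_equal(mean_snp_count_per_window(w[c(3, 1, 2), ]), 6)
  expect_equal(mean_snp_count_per_window(w[2, ]), 6)
  expect_error(mean_snp_count_per_window(w[0, ]), "no windows")
})

test_that("peak calling finds run maxima and verifies against window thresholds", {
  cfg <- window_config(1e5, 5e4)
  # chromosome A: 50 deep SNPs, 40 significant, inside one region
  posA <- seq(10000L, 90000L, length.out = 50)
  flagsA <- c(rep(TRUE, 40), rep(FALSE, 10))
  # chromosome B: 12 shallow SNPs, 1 significant -> ratio barely above the
  # genome threshold but far below its own window threshold
  posB <- seq(10000L, 90000L, length.out = 12)
  flagsB <- c(TRUE, rep(FALSE, 11))
  x <- rbind(stats_tbl_from("ChrA", posA, flagsA, depth = 30L),
             stats_tbl_from("ChrB", posB, flagsB, depth = 8L))
  class(x) <- c("snp_tbl", "data.frame")
  w <- build_windows(x, cfg)
  model <- null_model(replicates = 400, seed = 2)
  peaks <- call_peaks(w, "ratio", genome_threshold = 0.05, stats = x,
                      model = model)
  expect_equal(sort(unique(peaks$chrom)), c("ChrA", "ChrB"))
  pa <- peaks[peaks$chrom == "ChrA", ]
  pb <- peaks[peaks$chrom == "ChrB", ]
  expect_true(all(pa$verified))
  expect_gt(pa$value[1], pa$window_threshold[1])
  expect_false(any(pb$verified))  # 1/12 cannot clear a 12-SNP window threshold
  expect_true(all(peaks$value > 0.05))

  # all windows below the threshold: no peaks
  none <- call_peaks(w, "ratio", genome_threshold = 1.1, stats = x,
                     model = model)
  expect_equal(nrow(none), 0L)
})

test_that("windows truncated by the chromosome end cannot be peak windows", {
  cfg <- window_config(1e5, 1e4)
  pos <- seq(5000L, 395000L, by = 1000L)
  flags <- rep(FALSE, length(pos))
  flags[pos > 3e5] <- TRUE  # enrichment at the chromosome tail
  x <- stats_tbl_from("Chr01", pos, flags)
  w <- build_windows(x, cfg)
  peaks <- call_peaks(w, "ratio", genome_threshold = 0.1, verify = FALSE)
  last_full <- max(w$start[w$end <= max(pos) + cfg$step])
  expect_true(all(peaks$start <= last_full))
})

test_that("heterozygosity and contamination tracks partition each window", {
  set.seed(3)
  pos <- sort(sample.int(3e5, 300))
  cls <- sample(c("shared", "htSNP", "bsSNP"), 300, replace = TRUE,
                prob = c(0.6, 0.25, 0.15))
  x <- stats_tbl_from("Chr01", pos, runif(300) < 0.2)
  x$parent_class <- factor(cls, levels = c("shared", "htSNP", "bsSNP"))
  ht <- heterozygosity_track(x, window_config(1e5, 5e4))
  nz <- ht$total_snps > 0
  expect_equal(ht$het_fraction[nz] + ht$bs_fraction[nz] +
                 ht$shared_fraction[nz], rep(1, sum(nz)))
  expect_true(all(ht$ssnp_ht_ratio[nz] <= ht$het_fraction[nz] + 1e-12))
  # no htSNPs anywhere -> zero heterozygosity track
  x2 <- x
  x2$parent_class <- factor("shared", levels = levels(x$parent_class))
  ht2 <- heterozygosity_track(x2, window_config(1e5, 5e4))
  expect_true(all(ht2$het_fraction[ht2$total_snps > 0] == 0))
})
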