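test_that("two-ALT zero-REF records are recoded before genotype checks", {
  x <- snp_fixture(
    snp_row(ref = "A", alt = "T,G", b1 = c("T/G", "0,12,8", "40"),
            b2 = c("T/G", "0,7,9", "40")))
  y <- normalize_two_alt(x)
  expect_equal(y$REF, "T")
  expect_equal(y$ALT, "G")
  expect_equal(y$bulk1.AD, "12,8")
  expect_equal(y$bulk2.AD, "7,9")
  expect_equal(y$bulk1.GT, "T/G")  # genotype strings untouched

  # nonzero REF read anywhere violates the precondition
  bad <- snp_fixture(
    snp_row(ref = "A", alt = "T,G", b1 = c("T/G", "3,12,8", "40"),
            b2 = c("T/G", "0,7,9", "40")))
  expect_error(normalize_two_alt(bad), "REF reads")
})

test_that("each record is attributed to the first rule it fails, and counts conserve", {
  good <- function(pos) snp_row(pos = pos, b1 = c("A/T", "10,10", "40"),
                                b2 = c("A/A", "12,0", "40"),
                                p1 = c("A/A", "8,0", "50"),
                                p2 = c("T/T", "0,9", "50"))
  x <- snp_fixture(parents = TRUE,
    modifyList(good(10L), list(CHROM = "ChrMt")),                    # rule 1
    modifyList(good(20L), list(bulk1.AD = NA_character_)),           # rule 2
    snp_row(pos = 30L, b1 = c("T/T", "0,12", "40"),                  # rule 3
            b2 = c("T/T", "0,9", "40"), p1 = c("T/T", "0,8", "50"),
            p2 = c("T/T", "0,7", "50")),
    modifyList(good(40L), list(ALT = "T,G,C", bulk1.AD = "0,5,5,5",  # rule 4
                               bulk2.AD = "0,5,5,5", parent1.AD = "0,5,5,5",
                               parent2.AD = "0,5,5,5")),
    modifyList(good(50L), list(ALT = "T,G", bulk1.AD = "3,5,5",      # rule 5
                               bulk2.AD = "0,5,5", parent1.AD = "0,5,5",
                               parent2.AD = "0,5,5")),
    modifyList(good(60L), list(bulk1.GT = "C/C", bulk1.AD = "12,0")),# rule 6
    modifyList(good(70L), list(bulk1.GT = "A/T", bulk1.AD = "12,0")),# rule 7
    modifyList(good(80L), list(bulk1.GQ = 19L)),                     # rule 8
    modifyList(good(90L), list(bulk2.AD = "30,31", bulk2.GT = "A/T")), # rule 9
    modifyList(good(101L), list(parent1.GQ = 5L)),                   # parent GQ
    modifyList(good(110L), list(parent2.GT = "A/T",                  # rule 10
                                parent2.AD = "5,4")),
    good(120L))
  res <- filter_snps(x, filter_config(mean_coverage = 8), use_parents = TRUE)
  r <- res$report
  expect_equal(r$input, 12L)
  expect_equal(r$output, 1L)
  expect_equal(unname(r$removed[c("excluded_chrom", "missing_value",
                                  "zero_ref_single_alt", "multi_alt_3plus",
                                  "two_alt_nonzero_ref", "gt_ref_alt_mismatch",
                                  "gt_ad_inconsistent", "low_gq_bulk",
                                  "depth_cap", "low_gq_parent", "het_parent")]),
               rep(1L, 11))
  expect_equal(r$input, r$output + sum(r$removed))
  expect_equal(res$snps$POS, 120L)

  # filtering is idempotent
  res2 <- filter_snps(res$snps, filter_config(mean_coverage = 8),
                      use_parents = TRUE)
  expect_equal(sum(res2$report$removed), 0L)
  expect_equal(nrow(res2$snps), 1L)
})

test_that("depth cap and GQ floor use the configured thresholds", {
  x <- snp_fixture(
    snp_row(pos = 1L, b1 = c("A/T", "30,30", "40"), b2 = c("A/T", "5,5", "40")),
    snp_row(pos = 2L, b1 = c("A/T", "10,10", "40"), b2 = c("A/T", "5,5", "19")),
    snp_row(pos = 3L, b1 = c("A/T", "10,10", "40"), b2 = c("A/T", "5,5", "20")))
  res <- filter_snps(x, filter_config(gq_min = 20, depth_cap_multiplier = 6,
                                      mean_coverage = 8))
  expect_equal(unname(res$report$removed["depth_cap"]), 1L)   # 60 > 48
  expect_equal(unname(res$report$removed["low_gq_bulk"]), 1L) # 19 < 20
  expect_equal(res$snps$POS, 3L)                              # GQ 20 retained
})

test_that("mean coverage estimate is the per-role median depth", {
  x <- snp_fixture(snp_row(pos = 1, b1 = c("A/T", "4,4", "40")),
                   snp_row(pos = 2, b1 = c("A/T", "3,5", "40")),
                   snp_row(pos = 3, b1 = c("A/T", "6,2", "40")))
  expect_equal(estimate_mean_coverage(x, "bulk1"), 8)
  y <- snp_fixture(snp_row(pos = 1, b1 = c("A/T", "1,1", "40")),
                   snp_row(pos = 2, b1 = c("A/T", "4,4", "40")),
                   snp_row(pos = 3, b1 = c("A/T", "50,50", "40")))
  expect_equal(estimate_mean_coverage(y, "bulk1"), 8)  # robust to outliers
  expect_error(estimate_mean_coverage(y[0, ], "bulk1"), "no usable")
})

test_that("parent intersection matches on position and allele composition", {
  bulk <- snp_fixture(
    snp_row(pos = 100L), snp_row(pos = 200L), snp_row(pos = 300L))
  parents <- data.frame(CHROM = "Chr01", POS = c(100L, 200L), QUAL = 500,
                        REF = "A", ALT = c("T", "G"),
                        parent1.GT = "A/A", parent1.AD = "8,0",
                        parent1.GQ = 50L,
                        parent2.GT = c("T/T", "G/G"),
                        parent2.AD = "0,9", parent2.GQ = 50L,
                        stringsAsFactors = FALSE)
  class(parents) <- c("snp_tbl", "data.frame")
  attr(parents, "roles") <- sample_roles("b1", "b2", "parent1", "parent2")
  m <- intersect_with_parents(bulk, parents)
  expect_equal(m$POS, 100L)          # 200 differs in ALT, 300 is bulk-only
  expect_equal(m$parent1.AD, "8,0")  # parent calls attached
  expect_true(all(c("parent1.GT", "parent2.GQ") %in% names(m)))
})

test_that("AD/GT swapping re-anchors records to the reference parent", {
  x <- snp_fixture(parents = TRUE,
    snp_row(ref = "G", alt = "A", b1 = c("G/A", "19,9", "60"),
            b2 = c("G/A", "9,19", "50"), p1 = c("A/A", "0,8", "50"),
            p2 = c("G/G", "7,0", "50")),
    snp_row(pos = 200L, b1 = c("A/T", "10,10", "40"),
            b2 = c("A/T", "11,9", "40"), p1 = c("A/A", "8,0", "50"),
            p2 = c("T/T", "0,9", "50")))
  y <- swap_ref_alt(x)
  # row 1: reference parent holds the ALT allele -> swapped
  expect_equal(y$REF[1], "A")
  expect_equal(y$ALT[1], "G")
  expect_equal(y$bulk1.AD[1], "9,19")
  expect_equal(y$bulk2.AD[1], "19,9")
  expect_equal(y$bulk1.GT[1], "A/G")
  # row 2: reference parent already at REF -> identity
  expect_equal(y$bulk1.AD[2], "10,10")
  expect_equal(y$REF[2], "A")
  # anchored swapping is idempotent: everything already sits on the
  # reference parent's allele
  z <- swap_ref_alt(y)
  expect_equal(as.data.frame(z), as.data.frame(y), ignore_attr = TRUE)
  # the mechanical field reversal itself is an involution
  force_gt <- paste(y$ALT, y$ALT, sep = "/")
  flipped <- swap_ref_alt(y, parent_gt = force_gt)
  back <- swap_ref_alt(flipped, parent_gt = paste(flipped$ALT, flipped$ALT,
                                                  sep = "/"))
  expect_equal(as.data.frame(back), as.data.frame(y), ignore_attr = TRUE)
  # total depth is never changed
  tot <- function(t) sapply(strsplit(t$bulk1.AD, ","),
                            function(p) sum(as.integer(p)))
  expect_equal(tot(y), tot(x))
  # every swapped record's REF allele equals the reference parent's allele
  p1a <- sub("/.*", "", y$parent1.GT)
  expect_true(all(p1a == y$REF))

  het <- snp_fixture(parents = TRUE,
    snp_row(p1 = c("A/T", "4,5", "50"), p2 = c("T/T", "0,9", "50")))
  expect_error(swap_ref_alt(het), "homozygous")
})

test_that("parent-origin classification is exhaustive and disjoint", {
  bulk <- snp_fixture(snp_row(pos = 100L), snp_row(pos = 200L),
                      snp_row(pos = 300L))
  parents <- data.frame(CHROM = "Chr01", POS = c(100L, 200L), QUAL = 500,
                        REF = "A", ALT = "T",
                        parent1.GT = c("A/A", "A/A"),
                        parent1.AD = c("8,0", "8,0"),
                        parent1.GQ = c(50L, 50L),
                        parent2.GT = c("T/T", "A/T"),
                        parent2.AD = c("0,9", "4,5"),
                        parent2.GQ = c(50L, 50L),
                        stringsAsFactors = FALSE)
  class(parents) <- c("snp_tbl", "data.frame")
  y <- classify_parent_origin(bulk, parents)
  expect_equal(as.character(y$parent_class), c("shared", "htSNP", "bsSNP"))
  expect_equal(sum(table(y$parent_class)), nrow(bulk))
})
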