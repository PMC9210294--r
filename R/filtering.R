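#' SNP filtering configuration
#'
#' @param gq_min genotype-quality floor; calls with GQ below it in any bulk
#'   (and, after parent intersection, any parent) are removed. Default 20.
#' @param depth_cap_multiplier maximum per-bulk total depth (AD_ref + AD_alt)
#'   as a multiple of the average sequencing coverage. Default 6.
#' @param mean_coverage average sequencing coverage of the run (X-fold).
#'   Either a single value or a named vector with entries `bulk1`/`bulk2`.
#'   When `NULL`, it is estimated per bulk as the median pre-filter SNP depth
#'   (see [estimate_mean_coverage()]).
#' @param exclude_chroms character vector of substrings; chromosomes whose
#'   name contains any of them (case-insensitive) are treated as
#'   organellar/unplaced and removed.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(gq_min = 20L, depth_cap_multiplier = 6,
                          mean_coverage = NULL,
                          exclude_chroms = c("Mt", "Pt", "chloroplast",
                                             "mitochond")) {
  stopifnot(gq_min >= 0, depth_cap_multiplier > 0)
  structure(list(gq_min = as.integer(gq_min),
                 depth_cap_multiplier = depth_cap_multiplier,
                 mean_coverage = mean_coverage,
                 exclude_chroms = exclude_chroms),
            class = "filter_config")
}

#' Estimate average coverage for one sample role
#'
#' Fallback when the run-level sequencing coverage is not supplied: the median
#' of per-SNP total depth (sum of the AD values) across pre-filter records,
#' which is robust to the high-depth artifact tail.
#'
#' @param x a `snp_tbl`.
#' @param role role name, e.g. `"bulk1"`.
#' @return a single numeric coverage estimate.
#' @export
estimate_mean_coverage <- function(x, role) {
  col <- paste0(role, ".AD")
  if (!col %in% names(x)) stop("no AD column for role ", role)
  depths <- vapply(.split_ad(x[[col]]), function(a)
    if (anyNA(a)) NA_real_ else sum(a), numeric(1))
  depths <- depths[!is.na(depths)]
  if (!length(depths)) stop("no usable AD records to estimate coverage for ", role)
  stats::median(depths)
}

# Parsed per-sample calls for all roles present in x:
# list(role = list(gt = n x 2 char matrix, ad = list of int vectors, gq = int))
.parse_calls <- function(x) {
  out <- list()
  for (role in .tbl_roles(x)) {
    out[[role]] <- list(gt = .split_gt(x[[paste0(role, ".GT")]]),
                        ad = .split_ad(x[[paste0(role, ".AD")]]),
                        gq = x[[paste0(role, ".GQ")]])
  }
  out
}

.n_alt <- function(alt) lengths(strsplit(alt, ",", fixed = TRUE))

#' Replace the REF allele of two-ALT, zero-REF-read records
#'
#' Records whose ALT field holds two alleles while no sample has any REF read
#' are recoded as biallelic: the REF allele becomes the former first ALT
#' allele, the ALT allele becomes the former second one, and the leading REF
#' count (and its comma) is dropped from every AD field. Genotype strings are
#' untouched; their alleles now span the new REF/ALT pair. This normalization
#' runs before the genotype-agreement checks.
#'
#' @param x a `snp_tbl` whose rows all satisfy the precondition (exactly two
#'   ALT alleles, zero REF reads in every mapped sample).
#' @return the recoded `snp_tbl`.
#' @export
normalize_two_alt <- function(x) {
  if (!nrow(x)) return(x)
  elig <- .two_alt_zero_ref(x)
  if (!all(elig))
    stop("normalize_two_alt applied to a record with REF reads or ALT count != 2")
  .normalize_two_alt_rows(x, rep(TRUE, nrow(x)))
}

# Rows with exactly two ALT alleles and zero REF reads in every mapped sample.
.two_alt_zero_ref <- function(x) {
  calls <- .parse_calls(x)
  elig <- .n_alt(x$ALT) == 2L
  for (role in names(calls)) {
    ref_reads <- vapply(calls[[role]]$ad, function(a)
      if (anyNA(a)) NA_integer_ else a[1], integer(1))
    elig <- elig & !is.na(ref_reads) & ref_reads == 0L
  }
  elig
}

.normalize_two_alt_rows <- function(x, rows) {
  idx <- which(rows)
  if (!length(idx)) return(x)
  alts <- strsplit(x$ALT[idx], ",", fixed = TRUE)
  x$REF[idx] <- vapply(alts, `[`, character(1), 1L)
  x$ALT[idx] <- vapply(alts, `[`, character(1), 2L)
  for (role in .tbl_roles(x)) {
    col <- paste0(role, ".AD")
    x[[col]][idx] <- sub("^[0-9]+,", "", x[[col]][idx])
  }
  x
}

#' Apply the SNP hygiene filter
#'
#' Removes records in a fixed rule order, attributing each record to the
#' first rule it fails, so the removal report is deterministic:
#' \enumerate{
#'   \item organellar / unplaced chromosomes (`exclude_chroms`);
#'   \item a missing value in any used field (CHROM, POS, REF, ALT, or any
#'     mapped sample's GT/AD/GQ, including malformed AD lengths);
#'   \item (after [normalize_two_alt()] of eligible records) zero REF reads
#'     with a single ALT allele in all mapped samples;
#'   \item three or more ALT alleles;
#'   \item two ALT alleles with a nonzero REF read in any sample;
#'   \item genotypes disagreeing with the REF/ALT bases;
#'   \item genotypes inconsistent with the AD values (a homozygous call needs
#'     the non-called allele's depth to be 0 and the called allele's depth
#'     positive; a heterozygous call needs both depths positive);
#'   \item GQ below `gq_min` in any bulk;
#'   \item per-bulk total depth above `depth_cap_multiplier` times the average
#'     coverage;
#'   \item when `use_parents`, records heterozygous in any parent (and, when
#'     parent calls carry GQ, parental GQ below `gq_min`).
#' }
#'
#' @param x a `snp_tbl`.
#' @param cfg a [filter_config()].
#' @param use_parents apply the parent-based rules when parent columns are
#'   present. Default: parents present in `x`.
#' @param parent_gq apply the parental GQ floor (default TRUE). The
#'   orchestrated with-parents pipeline sets this to FALSE when filtering the
#'   parental dataset, because the common SNP set is identified before the
#'   low-GQ parental records are dropped.
#' @return a list with elements `snps` (the filtered `snp_tbl`) and `report`
#'   (a `filter_report` of per-rule removal counts).
#' @export
filter_snps <- function(x, cfg = filter_config(),
                        use_parents = length(.parent_roles(x)) > 0,
                        parent_gq = TRUE) {
  stopifnot(inherits(cfg, "filter_config"))
  n_in <- nrow(x)
  bulks <- .bulk_roles(x)
  parents <- if (use_parents) .parent_roles(x) else character(0)
  removed <- c(excluded_chrom = 0L, missing_value = 0L,
               zero_ref_single_alt = 0L, multi_alt_3plus = 0L,
               two_alt_nonzero_ref = 0L, gt_ref_alt_mismatch = 0L,
               gt_ad_inconsistent = 0L, low_gq_bulk = 0L, depth_cap = 0L,
               low_gq_parent = 0L, het_parent = 0L)

  drop_rows <- function(x, bad, rule) {
    removed[rule] <<- removed[rule] + sum(bad)
    x[!bad, , drop = FALSE]
  }

  # 1. organellar / unplaced chromosomes
  bad <- Reduce(`|`, lapply(cfg$exclude_chroms, function(p)
    grepl(p, x$CHROM, ignore.case = TRUE, fixed = FALSE)), rep(FALSE, nrow(x)))
  x <- drop_rows(x, bad, "excluded_chrom")

  # 2. missing values in any used field (incl. malformed AD lengths)
  calls <- .parse_calls(x)
  bad <- is.na(x$CHROM) | is.na(x$POS) | .is_missing(x$REF) | .is_missing(x$ALT)
  n_all <- 1L + .n_alt(x$ALT)
  for (role in names(calls)) {
    cl <- calls[[role]]
    ad_bad <- vapply(cl$ad, anyNA, logical(1)) | lengths(cl$ad) != n_all
    bad <- bad | is.na(cl$gt[, 1]) | is.na(cl$gq) | ad_bad
  }
  x <- drop_rows(x, bad, "missing_value")

  # two-ALT REF replacement (before the genotype-agreement checks)
  x <- .normalize_two_alt_rows(x, .two_alt_zero_ref(x))
  calls <- .parse_calls(x)
  n_alt <- .n_alt(x$ALT)
  ref_reads <- lapply(calls, function(cl)
    vapply(cl$ad, `[`, integer(1), 1L))

  # 3. zero REF reads with a single ALT allele in all mapped samples
  bad <- n_alt == 1L & Reduce(`&`, lapply(ref_reads, `==`, 0L),
                              rep(TRUE, nrow(x)))
  keep <- !bad
  x <- drop_rows(x, bad, "zero_ref_single_alt")
  calls <- lapply(calls, function(cl)
    list(gt = cl$gt[keep, , drop = FALSE], ad = cl$ad[keep], gq = cl$gq[keep]))
  n_alt <- n_alt[keep]

  refilter <- function(keep) {
    calls <<- lapply(calls, function(cl)
      list(gt = cl$gt[keep, , drop = FALSE], ad = cl$ad[keep], gq = cl$gq[keep]))
    n_alt <<- n_alt[keep]
  }

  # 4. three or more ALT alleles
  bad <- n_alt >= 3L
  x <- drop_rows(x, bad, "multi_alt_3plus"); refilter(!bad)

  # 5. two ALT alleles with a nonzero REF read somewhere
  bad <- n_alt == 2L
  x <- drop_rows(x, bad, "two_alt_nonzero_ref"); refilter(!bad)

  # survivors are biallelic from here on
  # 6. genotype alleles must be drawn from {REF, ALT}
  bad <- rep(FALSE, nrow(x))
  for (role in names(calls)) {
    gt <- calls[[role]]$gt
    bad <- bad | !(gt[, 1] == x$REF | gt[, 1] == x$ALT) |
      !(gt[, 2] == x$REF | gt[, 2] == x$ALT)
  }
  x <- drop_rows(x, bad, "gt_ref_alt_mismatch"); refilter(!bad)

  # 7. genotype / AD consistency
  bad <- rep(FALSE, nrow(x))
  for (role in names(calls)) {
    gt <- calls[[role]]$gt
    ad_ref <- vapply(calls[[role]]$ad, `[`, integer(1), 1L)
    ad_alt <- vapply(calls[[role]]$ad, `[`, integer(1), 2L)
    hom_ref <- gt[, 1] == x$REF & gt[, 2] == x$REF
    hom_alt <- gt[, 1] == x$ALT & gt[, 2] == x$ALT
    het <- !hom_ref & !hom_alt
    ok <- (hom_ref & ad_ref > 0L & ad_alt == 0L) |
      (hom_alt & ad_alt > 0L & ad_ref == 0L) |
      (het & ad_ref > 0L & ad_alt > 0L)
    bad <- bad | !ok
  }
  x <- drop_rows(x, bad, "gt_ad_inconsistent"); refilter(!bad)

  # 8. GQ floor in any bulk
  if (length(bulks)) {
    bad <- rep(FALSE, nrow(x))
    for (role in bulks) bad <- bad | calls[[role]]$gq < cfg$gq_min
    x <- drop_rows(x, bad, "low_gq_bulk"); refilter(!bad)
  }

  # 9. depth cap in any bulk
  if (length(bulks)) {
    cov <- cfg$mean_coverage
    bad <- rep(FALSE, nrow(x))
    for (role in bulks) {
      cv <- if (is.null(cov)) estimate_mean_coverage(x, role)
            else if (!is.null(names(cov)) && role %in% names(cov)) cov[[role]]
            else unname(cov[1])
      depth <- vapply(calls[[role]]$ad, sum, integer(1))
      bad <- bad | depth > cfg$depth_cap_multiplier * cv
    }
    x <- drop_rows(x, bad, "depth_cap"); refilter(!bad)
  }

  # 10. parent-based rules
  if (length(parents)) {
    if (parent_gq) {
      bad <- rep(FALSE, nrow(x))
      for (role in parents) bad <- bad | calls[[role]]$gq < cfg$gq_min
      x <- drop_rows(x, bad, "low_gq_parent"); refilter(!bad)
    }

    bad <- rep(FALSE, nrow(x))
    for (role in parents) {
      gt <- calls[[role]]$gt
      bad <- bad | gt[, 1] != gt[, 2]
    }
    x <- drop_rows(x, bad, "het_parent"); refilter(!bad)
  }

  report <- structure(list(input = n_in, output = nrow(x), removed = removed),
                      class = "filter_report")
  list(snps = x, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("SNP filter report: ", x$input, " in, ", x$output, " out\n", sep = "")
  for (rule in names(x$removed)) {
    cat(sprintf("  %-22s %d\n", paste0(rule, ":"), x$removed[[rule]]))
  }
  invisible(x)
}

.key <- function(chrom, pos, ref, alt) {
  alleles <- mapply(function(r, a) paste(sort(c(r, strsplit(a, ",")[[1]])),
                                         collapse = "|"),
                    ref, alt, USE.NAMES = FALSE)
  paste(chrom, pos, alleles, sep = ":")
}

#' Intersect bulk SNPs with the parental SNP set
#'
#' Keeps the bulk records whose chromosome, coordinate, and allele composition
#' match a record in the parental dataset (the "common SNPs"), attaching the
#' parent calls so that AD/GT swapping and the heterozygous-parent rule can be
#' applied afterwards. The intersection runs before the parental GQ filter.
#'
#' @param bulk a filtered `snp_tbl` with bulk columns.
#' @param parents a filtered `snp_tbl` with parent columns.
#' @return a `snp_tbl` with both bulk and parent sample columns.
#' @export
intersect_with_parents <- function(bulk, parents) {
  kb <- .key(bulk$CHROM, bulk$POS, bulk$REF, bulk$ALT)
  kp <- .key(parents$CHROM, parents$POS, parents$REF, parents$ALT)
  m <- match(kb, kp)
  keep <- !is.na(m)
  out <- bulk[keep, , drop = FALSE]
  pm <- m[keep]
  for (role in .parent_roles(parents)) {
    for (field in c("GT", "AD", "GQ")) {
      col <- paste0(role, ".", field)
      out[[col]] <- parents[[col]][pm]
    }
  }
  roles <- .roles_attr(bulk) %||% sample_roles("bulk1", "bulk2")
  proles <- .roles_attr(parents)
  roles$parent1 <- proles$parent1 %||% "parent1"
  roles$parent2 <- proles$parent2 %||% "parent2"
  roles$reference_parent <- proles$reference_parent %||% "parent1"
  .as_snp_tbl(out, roles)
}

#' Swap REF/ALT orientation of AD and genotype fields
#'
#' Re-orients each biallelic record so that the reference parent's allele
#' occupies the REF position: wherever the reference parent is homozygous for
#' the ALT allele, the REF/ALT fields are exchanged and every sample's
#' genotype string (`"G/A"` to `"A/G"`) and AD pair (`"19,9"` to `"9,19"`) are
#' reversed. Swapping is an involution and never changes a sample's total
#' depth. It is meaningful only after filtering and only when parental data
#' are available.
#'
#' @param x a filtered, biallelic `snp_tbl` carrying parent columns (or see
#'   `parent_gt`).
#' @param parent_gt optional character vector of reference-parent genotypes
#'   (e.g. `"A/A"`), one per row, overriding the table's reference-parent
#'   column.
#' @return the re-oriented `snp_tbl`.
#' @export
swap_ref_alt <- function(x, parent_gt = NULL) {
  if (!nrow(x)) return(x)
  if (any(.n_alt(x$ALT) != 1L))
    stop("swap_ref_alt requires biallelic records")
  if (is.null(parent_gt)) {
    roles <- .roles_attr(x)
    rp <- roles$reference_parent %||% "parent1"
    col <- paste0(rp, ".GT")
    if (!col %in% names(x))
      stop("no reference-parent genotype column (", col, ") in the table")
    parent_gt <- x[[col]]
  }
  gt <- .split_gt(parent_gt)
  if (anyNA(gt[, 1]) || any(gt[, 1] != gt[, 2]))
    stop("reference parent must be homozygous at every locus ",
         "(heterozygous-parent records should have been filtered)")
  flip <- gt[, 1] == x$ALT
  bad <- !flip & gt[, 1] != x$REF
  if (any(bad))
    stop("reference-parent allele matches neither REF nor ALT at row ",
         which(bad)[1])
  if (!any(flip)) return(x)
  idx <- which(flip)
  old_ref <- x$REF[idx]
  x$REF[idx] <- x$ALT[idx]
  x$ALT[idx] <- old_ref
  for (role in .tbl_roles(x)) {
    gcol <- paste0(role, ".GT")
    acol <- paste0(role, ".AD")
    g <- .split_gt(x[[gcol]][idx])
    x[[gcol]][idx] <- paste(g[, 2], g[, 1], sep = "/")
    a <- .split_ad(x[[acol]][idx])
    x[[acol]][idx] <- vapply(a, function(p) paste(rev(p), collapse = ","),
                             character(1))
  }
  x
}

#' Classify bulk SNPs by parental origin
#'
#' Diagnoses the bulks-only SNP set against available parental data,
#' partitioning it into SNPs shared with homozygous parents (`"shared"`),
#' SNPs heterozygous in a parental line (`"htSNP"`), and bulk-specific SNPs
#' absent from the parental data or differing in allele composition
#' (`"bsSNP"`). The partition is exhaustive and disjoint.
#'
#' @param bulk a `snp_tbl` with bulk columns.
#' @param parents a `snp_tbl` with parent columns.
#' @return `bulk` with an added `parent_class` factor column.
#' @export
classify_parent_origin <- function(bulk, parents) {
  kb <- .key(bulk$CHROM, bulk$POS, bulk$REF, bulk$ALT)
  kp <- .key(parents$CHROM, parents$POS, parents$REF, parents$ALT)
  het <- rep(FALSE, nrow(parents))
  for (role in .parent_roles(parents)) {
    gt <- .split_gt(parents[[paste0(role, ".GT")]])
    het <- het | (!is.na(gt[, 1]) & gt[, 1] != gt[, 2])
  }
  m <- match(kb, kp)
  cls <- ifelse(is.na(m), "bsSNP", ifelse(het[m], "htSNP", "shared"))
  bulk$parent_class <- factor(cls, levels = c("shared", "htSNP", "bsSNP"))
  bulk
}
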