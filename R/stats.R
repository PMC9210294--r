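#' Two-sided Fisher's exact test on a 2x2 allele-depth table
#'
#' Computes, for each SNP, the two-sided exact P-value of the 2x2 table
#' `rbind(c(ad_ref1, ad_alt1), c(ad_ref2, ad_alt2))` by enumerating the
#' conditional hypergeometric distribution at fixed margins and summing the
#' probabilities of all outcomes no more likely than the observed one (the
#' same two-sided rule as [stats::fisher.test()]). The P-value is invariant
#' under a simultaneous REF/ALT swap in both bulks, which is why the
#' sSNP/totalSNP ratio method needs no parental genome sequences.
#'
#' Vectorized and memoized over duplicate tables, so millions of simulated
#' low-depth tables are cheap.
#'
#' @param ad_ref1,ad_alt1 REF/ALT read counts in bulk 1 (non-negative).
#' @param ad_ref2,ad_alt2 REF/ALT read counts in bulk 2.
#' @return numeric vector of P-values in (0, 1].
#' @export
#' @examples
#' fisher_pvalue(10, 10, 10, 10)  # identical proportions: 1
#' fisher_pvalue(19, 9, 9, 19)
fisher_pvalue <- function(ad_ref1, ad_alt1, ad_ref2, ad_alt2) {
  d1 <- ad_ref1 + ad_alt1
  d2 <- ad_ref2 + ad_alt2
  if (any(d1 < 1L) || any(d2 < 1L))
    stop("each bulk needs at least one read (zero-depth bulk)")
  key <- paste(ad_ref1, ad_alt1, ad_ref2, ad_alt2)
  first <- which(!duplicated(key))
  p_first <- vapply(first, function(i) {
    k <- ad_alt1[i] + ad_alt2[i]
    x <- max(0L, k - d2[i]):min(k, d1[i])
    dens <- stats::dhyper(x, d1[i], d2[i], k)
    min(1, sum(dens[dens <= stats::dhyper(ad_alt1[i], d1[i], d2[i], k) *
                      (1 + 1e-7)]))
  }, numeric(1))
  p_first[match(key, key[first])]
}

#' Allele frequency difference between bulks
#'
#' `delta_af = ad_alt2 / (ad_ref2 + ad_alt2) - ad_alt1 / (ad_ref1 + ad_alt1)`:
#' the ALT allele frequency in bulk 2 minus that in bulk 1. Its sign flips
#' exactly when both bulks' REF/ALT values are swapped, which is why the
#' allele frequency method requires parent-anchored AD swapping.
#'
#' @inheritParams fisher_pvalue
#' @return numeric vector in \[-1, 1\].
#' @export
delta_af <- function(ad_ref1, ad_alt1, ad_ref2, ad_alt2) {
  d1 <- ad_ref1 + ad_alt1
  d2 <- ad_ref2 + ad_alt2
  if (any(d1 < 1L) || any(d2 < 1L))
    stop("each bulk needs at least one read (zero-depth bulk)")
  ad_alt2 / d2 - ad_alt1 / d1
}

#' G-statistic of a 2x2 allele-depth table
#'
#' The likelihood-ratio statistic `G = 2 * sum(O * ln(O / E))` over the four
#' cells, with expectations `E = row total * column total / grand total` under
#' independence. Cells with `O = 0` contribute 0. Invariant under a
#' simultaneous REF/ALT swap in both bulks.
#'
#' @inheritParams fisher_pvalue
#' @return non-negative numeric vector.
#' @export
g_statistic <- function(ad_ref1, ad_alt1, ad_ref2, ad_alt2) {
  d1 <- ad_ref1 + ad_alt1
  d2 <- ad_ref2 + ad_alt2
  if (any(d1 < 1L) || any(d2 < 1L))
    stop("each bulk needs at least one read (zero-depth bulk)")
  n <- d1 + d2
  cr <- ad_ref1 + ad_ref2
  ca <- ad_alt1 + ad_alt2
  term <- function(o, e) ifelse(o == 0, 0, o * log(o / e))
  g <- 2 * (term(ad_ref1, d1 * cr / n) + term(ad_alt1, d1 * ca / n) +
            term(ad_ref2, d2 * cr / n) + term(ad_alt2, d2 * ca / n))
  pmax(g, 0)
}

#' Savitzky-Golay smoothing per chromosome
#'
#' Applies a Savitzky-Golay polynomial filter to a per-SNP series,
#' independently within each chromosome, over SNP index order (not physical
#' distance). Edge points are fitted with the filter's asymmetric
#' least-squares windows, so polynomials up to the filter order are
#' reproduced exactly everywhere. A chromosome with fewer points than the
#' window is returned unchanged.
#'
#' @param values numeric per-SNP series, ordered by position within
#'   chromosome.
#' @param chrom chromosome label per value (contiguous blocks).
#' @param window odd window length in SNPs (default 51).
#' @param order polynomial order (default 3, must be < `window`).
#' @return smoothed numeric vector, same length as `values`.
#' @export
smooth_by_chromosome <- function(values, chrom, window = 51L, order = 3L) {
  window <- as.integer(window)
  order <- as.integer(order)
  if (window <= 0L || window %% 2L == 0L)
    stop("smoothing window must be a positive odd integer")
  if (order < 0L || order >= window)
    stop("polynomial order must be non-negative and smaller than the window")
  stopifnot(length(values) == length(chrom))
  out <- values
  r <- rle(as.character(chrom))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(starts)) {
    idx <- starts[i]:ends[i]
    if (length(idx) >= window)
      out[idx] <- signal::sgolayfilt(values[idx], p = order, n = window)
  }
  out
}

#' Flag significant SNPs
#'
#' Marks a SNP significant (`is_ssnp`) when its smoothed Fisher P-value falls
#' strictly below `alpha_real` (ties at the threshold are non-significant).
#'
#' @param x a `snp_tbl` carrying a `fisher_p_smoothed` column.
#' @param alpha_real per-SNP significance level in (0, 1); default 0.01.
#' @return `x` with a logical `is_ssnp` column.
#' @export
flag_ssnps <- function(x, alpha_real = 0.01) {
  if (!is.numeric(alpha_real) || length(alpha_real) != 1L ||
      alpha_real <= 0 || alpha_real >= 1)
    stop("alpha_real must lie strictly between 0 and 1")
  if (!"fisher_p_smoothed" %in% names(x))
    stop("x carries no fisher_p_smoothed column; run snp_stats() first")
  x$is_ssnp <- x$fisher_p_smoothed < alpha_real
  x
}

# Extract the four bulk AD counts from a filtered biallelic snp_tbl.
.bulk_ad <- function(x) {
  ad1 <- .split_ad(x$bulk1.AD)
  ad2 <- .split_ad(x$bulk2.AD)
  list(ref1 = vapply(ad1, `[`, integer(1), 1L),
       alt1 = vapply(ad1, `[`, integer(1), 2L),
       ref2 = vapply(ad2, `[`, integer(1), 1L),
       alt2 = vapply(ad2, `[`, integer(1), 2L))
}

#' Per-SNP association statistics
#'
#' Computes, for every filtered biallelic SNP, the two-sided Fisher exact
#' P-value, the allele frequency difference, and the G-statistic from the
#' four bulk AD values, smooths each series per chromosome with a
#' Savitzky-Golay filter, and flags sSNPs on the smoothed P-values.
#' Smoothed P-values are clamped into \[0, 1\].
#'
#' @param x a filtered `snp_tbl` (biallelic, bulk columns present, sorted by
#'   chromosome and position).
#' @param alpha per-SNP significance level for sSNP flagging (default 0.01).
#' @param sg_window,sg_order Savitzky-Golay window length (SNPs) and
#'   polynomial order.
#' @return `x` with columns `fisher_p`, `delta_af`, `g_stat`, their
#'   `_smoothed` variants, and `is_ssnp`.
#' @export
snp_stats <- function(x, alpha = 0.01, sg_window = 51L, sg_order = 3L) {
  if (!nrow(x)) stop("empty SNP table")
  ad <- .bulk_ad(x)
  x$fisher_p <- fisher_pvalue(ad$ref1, ad$alt1, ad$ref2, ad$alt2)
  x$delta_af <- delta_af(ad$ref1, ad$alt1, ad$ref2, ad$alt2)
  x$g_stat <- g_statistic(ad$ref1, ad$alt1, ad$ref2, ad$alt2)
  x$fisher_p_smoothed <- pmin(pmax(
    smooth_by_chromosome(x$fisher_p, x$CHROM, sg_window, sg_order), 0), 1)
  x$delta_af_smoothed <-
    smooth_by_chromosome(x$delta_af, x$CHROM, sg_window, sg_order)
  x$g_stat_smoothed <-
    smooth_by_chromosome(x$g_stat, x$CHROM, sg_window, sg_order)
  flag_ssnps(x, alpha)
}
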