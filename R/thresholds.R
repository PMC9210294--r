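#' Null model for Monte-Carlo threshold estimation
#'
#' Describes the no-association null under which allele depths are simulated:
#' each SNP keeps its observed per-bulk total depth, and ALT reads are drawn
#' binomially at the population ALT frequency (0.5 for an F2; set 0.25/0.75
#' for backcross designs).
#'
#' @param alt_freq population ALT allele frequency under the null (default
#'   0.5 for an F2).
#' @param replicates Monte-Carlo repetitions (default 10000).
#' @param alpha_sim sSNP-calling level inside the ratio simulations (default
#'   0.10, deliberately looser than the real-data level so thresholds are
#'   conservative).
#' @param ratio_percentile percentile of simulated sSNP/totalSNP ratios used
#'   as the ratio threshold (default 99.5).
#' @param delta_af_ci two-sided confidence level for the allele frequency
#'   difference band, in percent (default 99).
#' @param g_percentile percentile for the G-statistic threshold (default
#'   99.5).
#' @param seed optional root seed; when set, every threshold operation
#'   re-seeds deterministically from it, so estimates are reproducible in
#'   isolation.
#' @return an object of class `null_model`.
#' @export
null_model <- function(alt_freq = 0.5, replicates = 10000L, alpha_sim = 0.10,
                       ratio_percentile = 99.5, delta_af_ci = 99,
                       g_percentile = 99.5, seed = NULL) {
  stopifnot(alt_freq > 0, alt_freq < 1, replicates >= 1,
            alpha_sim > 0, alpha_sim < 1,
            ratio_percentile > 0, ratio_percentile < 100,
            delta_af_ci > 0, delta_af_ci < 100,
            g_percentile > 0, g_percentile < 100)
  structure(list(alt_freq = alt_freq, replicates = as.integer(replicates),
                 alpha_sim = alpha_sim, ratio_percentile = ratio_percentile,
                 delta_af_ci = delta_af_ci, g_percentile = g_percentile,
                 seed = seed),
            class = "null_model")
}

.maybe_seed <- function(model, offset) {
  if (!is.null(model$seed)) set.seed((as.integer(model$seed) + offset) %% .Machine$integer.max)
  if (model$replicates < 100L)
    warning("fewer than 100 replicates: percentile estimates are unstable")
  invisible(NULL)
}

#' Simulate allele depths under the null
#'
#' Draws the ALT read count binomially with size `total_depth` and success
#' probability `alt_freq`; the REF count is the remainder. Vectorized over
#' `total_depth`.
#'
#' @param total_depth integer vector of per-SNP total depths (all >= 1).
#' @param alt_freq ALT allele frequency in the population.
#' @return a list with integer vectors `ref` and `alt`.
#' @export
simulate_allele_depths <- function(total_depth, alt_freq) {
  if (any(total_depth < 1L)) stop("total_depth must be >= 1")
  stopifnot(alt_freq >= 0, alt_freq <= 1)
  alt <- stats::rbinom(length(total_depth), total_depth, alt_freq)
  list(ref = as.integer(total_depth - alt), alt = as.integer(alt))
}

.threshold_estimate <- function(statistic, scope, lower = NA_real_,
                                upper = NA_real_, model, n_snps = NA_integer_) {
  structure(list(statistic = statistic, scope = scope,
                 lower = lower, upper = upper,
                 replicates = model$replicates, alpha_sim = model$alpha_sim,
                 seed = model$seed, n_snps = n_snps),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("%s threshold (%s scope, %d replicates): ",
              x$statistic, x$scope, x$replicates))
  if (!is.na(x$lower)) cat(sprintf("[%.4g, %.4g]\n", x$lower, x$upper))
  else cat(sprintf("%.4g\n", x$upper))
  invisible(x)
}

# Simulated sSNP/totalSNP ratios for a SNP set whose per-bulk depths are laid
# out replicate-major: d1, d2 have length n_snps * reps (or n_snps, recycled).
# Chunked so the intermediate vectors stay bounded.
.sim_ratios <- function(d1, d2, n_snps, reps, model) {
  ratios <- numeric(reps)
  chunk <- max(1L, min(reps, as.integer(ceiling(2e6 / n_snps))))
  done <- 0L
  recycle <- length(d1) == n_snps
  while (done < reps) {
    r <- min(chunk, reps - done)
    if (recycle) {
      dd1 <- rep.int(d1, r)
      dd2 <- rep.int(d2, r)
    } else {
      idx <- (done * n_snps + 1L):((done + r) * n_snps)
      dd1 <- d1[idx]
      dd2 <- d2[idx]
    }
    a1 <- stats::rbinom(length(dd1), dd1, model$alt_freq)
    a2 <- stats::rbinom(length(dd2), dd2, model$alt_freq)
    pv <- fisher_pvalue(dd1 - a1, a1, dd2 - a2, a2)
    sig <- matrix(pv < model$alpha_sim, nrow = n_snps)
    ratios[done + seq_len(r)] <- colMeans(sig)
    done <- done + r
  }
  ratios
}

#' Genome-wide sSNP/totalSNP ratio threshold
#'
#' In each replicate, samples (with replacement) as many SNPs from the whole
#' dataset as an average sliding window holds, simulates each sampled SNP's
#' allele depths under the null at its observed per-bulk depths, calls sSNPs
#' with Fisher's exact test at `alpha_sim`, and records the sSNP/totalSNP
#' ratio. The threshold is the `ratio_percentile` (nearest-rank) of the
#' replicate ratios; windows above it are candidate peaks.
#'
#' @param x a `snp_tbl` with bulk AD columns (the filtered dataset).
#' @param mean_window_snp_count average SNP count per sliding window (see
#'   [mean_snp_count_per_window()]).
#' @param model a [null_model()].
#' @return a `threshold_estimate` (upper bound only).
#' @export
genome_wide_ratio_threshold <- function(x, mean_window_snp_count,
                                        model = null_model()) {
  stopifnot(nrow(x) >= 1, mean_window_snp_count >= 1)
  .maybe_seed(model, 2L)
  ad <- .bulk_ad(x)
  d1 <- ad$ref1 + ad$alt1
  d2 <- ad$ref2 + ad$alt2
  m <- as.integer(round(mean_window_snp_count))
  reps <- model$replicates
  idx <- sample.int(nrow(x), m * reps, replace = TRUE)
  ratios <- .sim_ratios(d1[idx], d2[idx], m, reps, model)
  .threshold_estimate("ratio", "genome",
                      upper = q_nearest_rank(ratios, model$ratio_percentile),
                      model = model, n_snps = m)
}

#' Sliding-window sSNP/totalSNP ratio threshold
#'
#' Same procedure as [genome_wide_ratio_threshold()] but without sampling:
#' each replicate simulates exactly the window's own SNPs at their observed
#' depths. Used to verify candidate peaks found with the genome-wide
#' threshold.
#'
#' @param x a `snp_tbl` holding the SNPs of one sliding window (non-empty).
#' @param model a [null_model()].
#' @return a `threshold_estimate` (upper bound only).
#' @export
window_ratio_threshold <- function(x, model = null_model()) {
  if (!nrow(x)) stop("empty window")
  .maybe_seed(model, 3L)
  ad <- .bulk_ad(x)
  d1 <- ad$ref1 + ad$alt1
  d2 <- ad$ref2 + ad$alt2
  ratios <- .sim_ratios(d1, d2, nrow(x), model$replicates, model)
  .threshold_estimate("ratio", "window",
                      upper = q_nearest_rank(ratios, model$ratio_percentile),
                      model = model, n_snps = nrow(x))
}

#' Per-SNP allele-frequency-difference and G-statistic thresholds
#'
#' For every SNP, simulates `replicates` null allele-depth tables at the
#' SNP's observed per-bulk depths, and takes the two-sided `delta_af_ci`
#' confidence band of the simulated allele frequency differences and the
#' `g_percentile` (nearest-rank) of the simulated G-statistics. The
#' per-chromosome threshold series are then smoothed with the same
#' Savitzky-Golay settings as the observed tracks, giving smooth threshold
#' curves.
#'
#' @param x a filtered `snp_tbl`, sorted by chromosome and position.
#' @param model a [null_model()].
#' @param sg_window,sg_order smoothing settings (match those used for the
#'   observed statistics).
#' @return `x` with columns `delta_af_lo`, `delta_af_hi`, `g_thresh`.
#' @export
snp_level_thresholds <- function(x, model = null_model(),
                                 sg_window = 51L, sg_order = 3L) {
  if (!nrow(x)) stop("empty SNP table")
  .maybe_seed(model, 1L)
  ad <- .bulk_ad(x)
  d1 <- ad$ref1 + ad$alt1
  d2 <- ad$ref2 + ad$alt2
  n <- nrow(x)
  reps <- model$replicates
  p <- model$alt_freq
  a1 <- matrix(stats::rbinom(n * reps, d1, p), nrow = n)
  a2 <- matrix(stats::rbinom(n * reps, d2, p), nrow = n)
  daf <- a2 / d2 - a1 / d1
  # G on the simulated tables, computed column-block-wise to bound memory
  g <- matrix(0, n, reps)
  step <- max(1L, as.integer(ceiling(2e6 / n)))
  for (j0 in seq(1L, reps, by = step)) {
    j <- j0:min(reps, j0 + step - 1L)
    g[, j] <- matrix(g_statistic(rep.int(d1, length(j)) - a1[, j],
                                 as.vector(a1[, j]),
                                 rep.int(d2, length(j)) - a2[, j],
                                 as.vector(a2[, j])), nrow = n)
  }
  lo_p <- (100 - model$delta_af_ci) / 2
  hi_p <- 100 - lo_p
  row_rank <- function(m, p) apply(m, 1L, function(v)
    sort(v)[ceiling(p / 100 * length(v))])
  daf_lo <- row_rank(daf, lo_p)
  daf_hi <- row_rank(daf, hi_p)
  g_thr <- row_rank(g, model$g_percentile)
  x$delta_af_lo <- smooth_by_chromosome(daf_lo, x$CHROM, sg_window, sg_order)
  x$delta_af_hi <- smooth_by_chromosome(daf_hi, x$CHROM, sg_window, sg_order)
  x$g_thresh <- smooth_by_chromosome(g_thr, x$CHROM, sg_window, sg_order)
  x
}
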