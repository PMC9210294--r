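#' Sliding window configuration
#'
#' Defaults follow the rice settings (2 Mb windows advanced by 10 kb); the
#' `"maize"` preset uses 5 Mb windows for the larger genome.
#'
#' @param window_size window width in bp (default 2e6).
#' @param step increment between window starts in bp (default 1e4).
#' @param preset optional name (`"rice"` or `"maize"`) overriding both.
#' @return an object of class `window_config`.
#' @export
window_config <- function(window_size = 2e6, step = 1e4, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("rice", "maize"))
    if (preset == "maize") { window_size <- 5e6; step <- 1e4 }
    else { window_size <- 2e6; step <- 1e4 }
  }
  stopifnot(window_size > 0, step > 0, step <= window_size)
  structure(list(window_size = as.numeric(window_size),
                 step = as.numeric(step)),
            class = "window_config")
}

#' sSNP/totalSNP ratio
#'
#' The window-level enrichment statistic of the significant-SNP method: the
#' count of significant SNPs over the count of all SNPs in a window.
#' `NA` where a window holds no SNPs.
#'
#' @param ssnp_count,total_snp_count non-negative integer vectors.
#' @return numeric vector of ratios in \[0, 1\].
#' @export
#' @examples
#' ssnp_ratio(675, 1139)  # 0.5926 at the rice chromosome-11 peak window
ssnp_ratio <- function(ssnp_count, total_snp_count) {
  stopifnot(all(ssnp_count >= 0), all(ssnp_count <= total_snp_count | total_snp_count == 0))
  ifelse(total_snp_count > 0, ssnp_count / total_snp_count, NA_real_)
}

# Aggregate per-SNP columns into sliding windows on one chromosome.
# pos must be sorted ascending. Returns start vector + per-window sums/counts.
.window_starts <- function(max_pos, cfg) {
  seq(1, max_pos, by = cfg$step)
}

.window_agg <- function(pos, values, starts, width) {
  csum <- rbind(0, apply(values, 2L, cumsum))
  lo <- findInterval(starts - 1, pos)      # SNPs strictly before start
  hi <- findInterval(starts + width - 1, pos)  # SNPs with pos < start+width
  list(n = hi - lo, sums = csum[hi + 1L, , drop = FALSE] -
         csum[lo + 1L, , drop = FALSE])
}

#' Build sliding windows over per-SNP statistics
#'
#' Windows start at position 1 on each chromosome and advance by `step` until
#' the chromosome's last SNP is covered (1-based, half-open intervals
#' `[start, start + window_size)`); trailing SNP-free windows are dropped but
#' interior empty windows are kept (ratio `NA`). Each window aggregates the
#' SNP count, sSNP count, their ratio, and the means of whatever smoothed
#' statistic and threshold columns are present (`delta_af_smoothed`,
#' `g_stat_smoothed`, `delta_af_lo`, `delta_af_hi`, `g_thresh`), since a
#' window's statistic and threshold are the averages over its SNPs.
#'
#' @param x a `snp_tbl` with statistics, sorted by chromosome then position.
#' @param cfg a [window_config()].
#' @return a data frame of class `bsa_windows`.
#' @export
build_windows <- function(x, cfg = window_config()) {
  stopifnot(inherits(cfg, "window_config"), nrow(x) >= 1)
  mean_cols <- c(mean_delta_af = "delta_af_smoothed",
                 mean_g = "g_stat_smoothed",
                 delta_af_lo = "delta_af_lo", delta_af_hi = "delta_af_hi",
                 g_thresh = "g_thresh")
  mean_cols <- mean_cols[mean_cols %in% names(x)]
  has_ssnp <- "is_ssnp" %in% names(x)
  out <- list()
  for (chrom in .chrom_order(x$CHROM)) {
    rows <- which(x$CHROM == chrom)
    pos <- x$POS[rows]
    if (is.unsorted(pos)) stop("SNPs not sorted by position on ", chrom)
    vals <- matrix(if (has_ssnp) as.numeric(x$is_ssnp[rows]) else 0,
                   ncol = 1L, dimnames = list(NULL, "ssnp"))
    for (nm in names(mean_cols)) {
      vals <- cbind(vals, x[[mean_cols[[nm]]]][rows])
      colnames(vals)[ncol(vals)] <- nm
    }
    starts <- .window_starts(max(pos), cfg)
    agg <- .window_agg(pos, vals, starts, cfg$window_size)
    w <- data.frame(chrom = chrom, start = starts,
                    end = starts + cfg$window_size,
                    total_snps = agg$n,
                    ssnps = if (has_ssnp) as.integer(agg$sums[, "ssnp"])
                            else NA_integer_,
                    stringsAsFactors = FALSE)
    w$ratio <- if (has_ssnp) ssnp_ratio(as.integer(agg$sums[, "ssnp"]),
                                        w$total_snps) else NA_real_
    for (nm in names(mean_cols)) {
      w[[nm]] <- ifelse(agg$n > 0, agg$sums[, nm] / agg$n, NA_real_)
    }
    out[[chrom]] <- w
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("bsa_windows", "data.frame")
  last_pos <- vapply(.chrom_order(x$CHROM), function(c0)
    max(x$POS[x$CHROM == c0]), numeric(1))
  attr(res, "last_snp_pos") <- last_pos
  attr(res, "config") <- cfg
  res
}

#' Average SNP count per sliding window
#'
#' Arithmetic mean of the per-window total SNP counts over all windows
#' (empty interior windows count as 0); the sample size used for the
#' genome-wide ratio threshold.
#'
#' @param windows a `bsa_windows` data frame.
#' @return a single numeric mean.
#' @export
mean_snp_count_per_window <- function(windows) {
  if (!nrow(windows)) stop("no windows")
  mean(windows$total_snps)
}

#' Call and verify significant peaks
#'
#' Finds maximal runs of consecutive windows exceeding the significance
#' threshold: for the ratio and G methods, windows whose statistic lies above
#' the threshold (genome-wide for the ratio, the window-averaged simulated
#' percentile for G); for the allele frequency method, windows whose mean
#' difference falls outside the simulated confidence band in either
#' direction. The window with the extreme statistic in each run is reported
#' as the peak. Ratio peaks are then verified against their own
#' window-specific simulated threshold ([window_ratio_threshold()]) when the
#' per-SNP data and a null model are supplied.
#'
#' @param windows a `bsa_windows` data frame.
#' @param statistic `"ratio"`, `"g"`, or `"delta_af"`.
#' @param genome_threshold for `"ratio"`: a `threshold_estimate` or a number.
#' @param stats the per-SNP `snp_tbl` (needed to verify ratio peaks).
#' @param model a [null_model()] (needed to verify ratio peaks).
#' @param verify verify ratio peaks by window-level simulation (default TRUE
#'   when `stats` and `model` are given).
#' @param position report the peak at the window `"start"` (default) or
#'   `"midpoint"`.
#' @return a data frame of class `bsa_peaks` (possibly empty): chrom,
#'   peak_pos, start, end, statistic, value, genome_threshold,
#'   window_threshold, verified.
#' @export
call_peaks <- function(windows, statistic = c("ratio", "g", "delta_af"),
                       genome_threshold = NULL, stats = NULL, model = NULL,
                       verify = !is.null(stats) && !is.null(model),
                       position = c("start", "midpoint")) {
  statistic <- match.arg(statistic)
  position <- match.arg(position)
  gt <- if (inherits(genome_threshold, "threshold_estimate"))
    genome_threshold$upper else genome_threshold
  sig <- switch(statistic,
    ratio = {
      if (is.null(gt)) stop("ratio peaks need a genome-wide threshold")
      !is.na(windows$ratio) & windows$ratio > gt
    },
    g = {
      if (!"g_thresh" %in% names(windows))
        stop("windows carry no g_thresh column")
      !is.na(windows$mean_g) & windows$mean_g > windows$g_thresh
    },
    delta_af = {
      if (!all(c("delta_af_lo", "delta_af_hi") %in% names(windows)))
        stop("windows carry no delta_af confidence band columns")
      !is.na(windows$mean_delta_af) &
        (windows$mean_delta_af > windows$delta_af_hi |
           windows$mean_delta_af < windows$delta_af_lo)
    })
  peaks <- list()
  for (chrom in unique(windows$chrom)) {
    rows <- which(windows$chrom == chrom)
    s <- sig[rows]
    if (!any(s)) next
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run <- rows[starts[k]:ends[k]]
      # windows truncated by the chromosome end hold only a handful of SNPs
      # and their ratio is unstable; a run's peak must be a fully covered
      # window, and a run with none yields no peak
      last_pos <- attr(windows, "last_snp_pos", exact = TRUE)
      cfg <- attr(windows, "config", exact = TRUE)
      if (!is.null(last_pos) && !is.null(cfg) && chrom %in% names(last_pos)) {
        full <- windows$end[run] <= last_pos[[chrom]] + cfg$step
        if (!any(full)) next
        run <- run[full]
      }
      excess <- switch(statistic,
        ratio = windows$ratio[run],
        g = windows$mean_g[run] - windows$g_thresh[run],
        delta_af = pmax(
          windows$mean_delta_af[run] - windows$delta_af_hi[run],
          windows$delta_af_lo[run] - windows$mean_delta_af[run]))
      # middle of the tied-maximum stretch: saturated tracks (every SNP
      # significant around a strong locus) otherwise bias the peak to the
      # run's left edge
      tied <- which(excess == max(excess))
      extreme <- run[tied[ceiling(length(tied) / 2)]]
      value <- switch(statistic, ratio = windows$ratio[extreme],
                      g = windows$mean_g[extreme],
                      delta_af = windows$mean_delta_af[extreme])
      wthr <- switch(statistic,
                     ratio = NA_real_,
                     g = windows$g_thresh[extreme],
                     delta_af = if (value > 0) windows$delta_af_hi[extreme]
                                else windows$delta_af_lo[extreme])
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = chrom,
        peak_pos = if (position == "start") windows$start[extreme]
                   else windows$start[extreme] +
                     (windows$end[extreme] - windows$start[extreme]) / 2,
        start = windows$start[extreme], end = windows$end[extreme],
        statistic = statistic, value = value,
        genome_threshold = gt %||% NA_real_,
        window_threshold = wthr,
        verified = statistic != "ratio",
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(chrom = character(), peak_pos = numeric(), start = numeric(),
               end = numeric(), statistic = character(), value = numeric(),
               genome_threshold = numeric(), window_threshold = numeric(),
               verified = logical(), stringsAsFactors = FALSE)
  if (statistic == "ratio" && verify && nrow(res)) {
    for (i in seq_len(nrow(res))) {
      in_win <- stats$CHROM == res$chrom[i] & stats$POS >= res$start[i] &
        stats$POS < res$end[i]
      wt <- window_ratio_threshold(stats[in_win, , drop = FALSE], model)
      res$window_threshold[i] <- wt$upper
      res$verified[i] <- res$value[i] > wt$upper
    }
  }
  rownames(res) <- NULL
  class(res) <- c("bsa_peaks", "data.frame")
  res
}

#' Per-window heterozygosity and contamination tracks
#'
#' Given bulk SNPs classified by [classify_parent_origin()], computes for
#' each sliding window the fraction of parent-heterozygous SNPs
#' (heterozygosity), the bulk-specific SNP count and fraction, the shared
#' fraction, and - when sSNP flags are present - the contributions of sSNPs
#' within htSNPs and within bsSNPs to the window's overall sSNP/totalSNP
#' ratio.
#'
#' @param x a `snp_tbl` with a `parent_class` column (and optionally
#'   `is_ssnp`), sorted by chromosome then position.
#' @param cfg a [window_config()].
#' @return a data frame with one row per window.
#' @export
heterozygosity_track <- function(x, cfg = window_config()) {
  stopifnot("parent_class" %in% names(x))
  out <- list()
  has_ssnp <- "is_ssnp" %in% names(x)
  for (chrom in .chrom_order(x$CHROM)) {
    rows <- which(x$CHROM == chrom)
    pos <- x$POS[rows]
    cls <- x$parent_class[rows]
    vals <- cbind(ht = as.numeric(cls == "htSNP"),
                  bs = as.numeric(cls == "bsSNP"),
                  shared = as.numeric(cls == "shared"),
                  ssnp_ht = if (has_ssnp)
                    as.numeric(cls == "htSNP" & x$is_ssnp[rows]) else 0,
                  ssnp_bs = if (has_ssnp)
                    as.numeric(cls == "bsSNP" & x$is_ssnp[rows]) else 0)
    starts <- .window_starts(max(pos), cfg)
    agg <- .window_agg(pos, vals, starts, cfg$window_size)
    n <- agg$n
    w <- data.frame(chrom = chrom, start = starts,
                    end = starts + cfg$window_size, total_snps = n,
                    htsnps = as.integer(agg$sums[, "ht"]),
                    bssnps = as.integer(agg$sums[, "bs"]),
                    het_fraction = ifelse(n > 0, agg$sums[, "ht"] / n, NA_real_),
                    bs_fraction = ifelse(n > 0, agg$sums[, "bs"] / n, NA_real_),
                    shared_fraction = ifelse(n > 0, agg$sums[, "shared"] / n,
                                             NA_real_),
                    ssnp_ht_ratio = ifelse(n > 0, agg$sums[, "ssnp_ht"] / n,
                                           NA_real_),
                    ssnp_bs_ratio = ifelse(n > 0, agg$sums[, "ssnp_bs"] / n,
                                           NA_real_),
                    stringsAsFactors = FALSE)
    out[[chrom]] <- w
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
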