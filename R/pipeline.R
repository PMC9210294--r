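#' Run the BSA-Seq genome scan
#'
#' Orchestrates the full analysis: read, filter, (optionally) intersect with
#' the parental SNP set and re-anchor REF/ALT by AD/GT swapping, compute and
#' smooth per-SNP statistics, flag sSNPs, estimate Monte-Carlo thresholds,
#' aggregate sliding windows, and call/verify peaks. The with-parents and
#' bulks-only entry modes differ only in whether `parents` is supplied; the
#' allele frequency method is refused without parents, because unanchored
#' REF/ALT orientation randomizes the sign of the frequency difference and
#' cancels the signal.
#'
#' @param bulks a `snp_tbl` with bulk columns, or a path to a TSV in the
#'   VariantsToTable dialect.
#' @param parents optional parental `snp_tbl` or TSV path.
#' @param roles a [sample_roles()] mapping; defaults to the one attached to
#'   `bulks` (required when `bulks` is a path).
#' @param filter a [filter_config()].
#' @param window a [window_config()].
#' @param model a [null_model()] for threshold simulation.
#' @param methods statistics to run: subset of `"ratio"`, `"g"`,
#'   `"delta_af"`.
#' @param alpha per-SNP significance level for sSNP flagging (default 0.01).
#' @param sg_window,sg_order Savitzky-Golay smoothing settings.
#' @param out_dir optional output directory; when given, the filtered SNP
#'   table, window table, peak table, run manifest (JSON), and track plots
#'   are written there.
#' @param seed optional seed driving all simulations of the run.
#' @return a list of class `bsa_run`: `snps` (filtered, with statistics),
#'   `windows`, `peaks`, `thresholds`, `reports`, `manifest`.
#' @export
run_bsaseq <- function(bulks, parents = NULL, roles = NULL,
                       filter = filter_config(), window = window_config(),
                       model = null_model(),
                       methods = c("ratio", "g", "delta_af"),
                       alpha = 0.01, sg_window = 51L, sg_order = 3L,
                       out_dir = NULL, seed = NULL) {
  methods <- match.arg(methods, c("ratio", "g", "delta_af"),
                       several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  use_parents <- !is.null(parents)
  if ("delta_af" %in% methods && !use_parents)
    stop("the allele frequency (delta_af) method requires parental data: ",
         "without parent-anchored AD/GT swapping the sign of the frequency ",
         "difference is arbitrary and no peak can be detected")
  if (is.character(bulks)) {
    if (is.null(roles)) stop("roles must be given when bulks is a file path")
    broles <- roles
    broles$parent1 <- broles$parent2 <- NULL
    bulks <- read_snp_table(bulks, broles)
  }
  if (is.character(parents)) {
    if (is.null(roles)) stop("roles must be given when parents is a file path")
    proles <- roles
    proles$bulk1 <- proles$bulk2 <- NULL
    parents <- read_snp_table(parents, proles)
  }

  # stage 1: filtering
  if (is.null(filter$mean_coverage)) {
    filter$mean_coverage <- c(bulk1 = estimate_mean_coverage(bulks, "bulk1"),
                              bulk2 = estimate_mean_coverage(bulks, "bulk2"))
  }
  fb <- filter_snps(bulks, filter, use_parents = FALSE)
  snps <- fb$snps
  reports <- list(bulks = fb$report)
  if (use_parents) {
    fp <- filter_snps(parents, filter, use_parents = TRUE, parent_gq = FALSE)
    reports$parents <- fp$report
    snps <- intersect_with_parents(snps, fp$snps)
    n_common <- nrow(snps)
    # parental GQ floor, applied after the common set is identified
    ok <- rep(TRUE, nrow(snps))
    for (role in .parent_roles(snps)) {
      ok <- ok & !is.na(snps[[paste0(role, ".GQ")]]) &
        snps[[paste0(role, ".GQ")]] >= filter$gq_min
    }
    snps <- snps[ok, , drop = FALSE]
    reports$intersection <- list(bulk_filtered = fb$report$output,
                                 parent_filtered = fp$report$output,
                                 common = n_common,
                                 low_gq_parent = sum(!ok))
    snps <- swap_ref_alt(snps)
  }
  if (!nrow(snps)) stop("no SNPs survive filtering")

  # stage 2: per-SNP statistics, smoothing, sSNP flagging
  snps <- snp_stats(snps, alpha = alpha, sg_window = sg_window,
                    sg_order = sg_order)
  if (any(c("g", "delta_af") %in% methods)) {
    snps <- snp_level_thresholds(snps, model, sg_window = sg_window,
                                 sg_order = sg_order)
  }

  # stage 3: windows, thresholds, peaks
  windows <- build_windows(snps, window)
  thresholds <- list()
  peaks <- list()
  if ("ratio" %in% methods) {
    gw <- genome_wide_ratio_threshold(snps, mean_snp_count_per_window(windows),
                                      model)
    thresholds$ratio_genome <- gw
    peaks$ratio <- call_peaks(windows, "ratio", genome_threshold = gw,
                              stats = snps, model = model)
  }
  if ("g" %in% methods) peaks$g <- call_peaks(windows, "g")
  if ("delta_af" %in% methods) peaks$delta_af <- call_peaks(windows, "delta_af")
  peak_tbl <- do.call(rbind, unname(peaks))
  if (is.null(peak_tbl)) peak_tbl <- call_peaks(windows[0, ], "g")

  manifest <- list(
    package = "bsaseqr",
    version = as.character(utils::packageVersion("bsaseqr")),
    r_version = as.character(getRversion()),
    seed = seed,
    methods = methods,
    alpha = alpha,
    sg_window = sg_window, sg_order = sg_order,
    filter = unclass(filter),
    window = unclass(window),
    null_model = unclass(model),
    use_parents = use_parents,
    counts = list(input = reports$bulks$input,
                  filtered = reports$bulks$output,
                  removed = as.list(reports$bulks$removed),
                  analyzed = nrow(snps),
                  ssnps = sum(snps$is_ssnp),
                  windows = nrow(windows),
                  peaks = nrow(peak_tbl),
                  verified_peaks = sum(peak_tbl$verified)))
  if (use_parents) {
    manifest$counts$parents <- reports$intersection
  }

  run <- structure(list(snps = snps, windows = windows, peaks = peak_tbl,
                        thresholds = thresholds, reports = reports,
                        manifest = manifest),
                   class = "bsa_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_snp_table(snps, file.path(out_dir, "filtered_snps.tsv"))
    data.table::fwrite(as.data.frame(windows),
                       file.path(out_dir, "windows.tsv"), sep = "\t")
    data.table::fwrite(as.data.frame(peak_tbl),
                       file.path(out_dir, "peaks.tsv"), sep = "\t")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    figs <- plot_tracks(windows, peaks = peak_tbl, out_dir = out_dir)
  }
  run
}

#' @export
print.bsa_run <- function(x, ...) {
  cat("BSA-Seq run:", x$manifest$counts$analyzed, "SNPs analyzed,",
      x$manifest$counts$ssnps, "sSNPs,", x$manifest$counts$windows,
      "windows\n")
  if (nrow(x$peaks)) {
    cat("peaks:\n")
    print(as.data.frame(x$peaks))
  } else cat("no significant peaks\n")
  invisible(x)
}

#' Per-chromosome sSNP summary
#'
#' Counts sSNPs and total SNPs per chromosome and their ratio, plus a
#' genome-wide row: the chromosome-level companion of the window scan.
#'
#' @param x a `snp_tbl` with an `is_ssnp` column.
#' @return a data frame: chrom, ssnps, total_snps, ratio.
#' @export
ssnp_summary <- function(x) {
  stopifnot("is_ssnp" %in% names(x))
  chroms <- .chrom_order(x$CHROM)
  tot <- vapply(chroms, function(c0) sum(x$CHROM == c0), integer(1))
  ss <- vapply(chroms, function(c0) sum(x$is_ssnp[x$CHROM == c0]), integer(1))
  out <- data.frame(chrom = c(chroms, "genome"),
                    ssnps = c(ss, sum(ss)),
                    total_snps = c(tot, sum(tot)),
                    stringsAsFactors = FALSE)
  out$ratio <- ssnp_ratio(out$ssnps, out$total_snps)
  rownames(out) <- NULL
  out
}

#' Plot genome-scan tracks
#'
#' One multi-panel figure per statistic: the per-window statistic against
#' genomic position, one panel per chromosome (natural sort order), with the
#' relevant threshold curve(s) overlaid - a horizontal line for the ratio's
#' genome-wide threshold, the window-averaged simulated threshold curve for
#' G, and the symmetric confidence band for the allele frequency difference.
#'
#' @param windows a `bsa_windows` data frame.
#' @param peaks optional `bsa_peaks` table; verified peaks are marked.
#' @param genome_ratio_threshold optional numeric or `threshold_estimate`
#'   drawn on the ratio panel.
#' @param out_dir optional directory to write one PNG per statistic.
#' @return named list of ggplot objects, invisibly.
#' @export
plot_tracks <- function(windows, peaks = NULL, genome_ratio_threshold = NULL,
                        out_dir = NULL) {
  if (!nrow(windows)) {
    warning("empty window table; nothing to plot")
    return(invisible(list()))
  }
  w <- as.data.frame(windows)
  w$chrom <- factor(w$chrom, levels = .chrom_order(w$chrom))
  w$mb <- (w$start + w$end) / 2 / 1e6
  gt <- if (inherits(genome_ratio_threshold, "threshold_estimate"))
    genome_ratio_threshold$upper else genome_ratio_threshold
  if (is.null(gt) && !is.null(peaks) && nrow(peaks)) {
    gr <- peaks$genome_threshold[peaks$statistic == "ratio"]
    if (length(gr)) gt <- gr[1]
  }
  figs <- list()
  base <- function(ycol) {
    ggplot2::ggplot(w[!is.na(w[[ycol]]), ],
                    ggplot2::aes(x = .data$mb, y = .data[[ycol]])) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::facet_wrap(~chrom, scales = "free_x") +
      ggplot2::labs(x = "position (Mb)") +
      ggplot2::theme_bw()
  }
  if (!all(is.na(w$ratio))) {
    p <- base("ratio") + ggplot2::labs(y = "sSNP/totalSNP ratio")
    if (!is.null(gt))
      p <- p + ggplot2::geom_hline(yintercept = gt, colour = "red",
                                   linetype = 2)
    figs$ratio <- p
  }
  if ("mean_g" %in% names(w) && !all(is.na(w$mean_g))) {
    p <- base("mean_g") + ggplot2::labs(y = "G-statistic")
    if ("g_thresh" %in% names(w))
      p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$g_thresh),
                                  colour = "red", linetype = 2)
    figs$g <- p
  }
  if ("mean_delta_af" %in% names(w) && !all(is.na(w$mean_delta_af))) {
    p <- base("mean_delta_af") +
      ggplot2::labs(y = "allele frequency difference")
    if (all(c("delta_af_lo", "delta_af_hi") %in% names(w))) {
      p <- p +
        ggplot2::geom_line(ggplot2::aes(y = .data$delta_af_lo),
                           colour = "red", linetype = 2) +
        ggplot2::geom_line(ggplot2::aes(y = .data$delta_af_hi),
                           colour = "red", linetype = 2)
    }
    figs$delta_af <- p
  }
  if (!is.null(peaks) && nrow(peaks)) {
    pk <- as.data.frame(peaks)
    pk$mb <- pk$peak_pos / 1e6
    for (st in names(figs)) {
      stat_name <- c(ratio = "ratio", g = "g", delta_af = "delta_af")[st]
      sub <- pk[pk$statistic == stat_name & pk$verified, , drop = FALSE]
      if (nrow(sub)) {
        sub$chrom <- factor(sub$chrom, levels = levels(w$chrom))
        figs[[st]] <- figs[[st]] +
          ggplot2::geom_vline(data = sub,
                              ggplot2::aes(xintercept = .data$mb),
                              colour = "blue", alpha = 0.4)
      }
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (st in names(figs)) {
      ggplot2::ggsave(file.path(out_dir, paste0("track_", st, ".png")),
                      figs[[st]], width = 9, height = 6, dpi = 120)
    }
  }
  invisible(figs)
}

#' @importFrom ggplot2 .data
NULL
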