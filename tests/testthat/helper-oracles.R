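# Independent oracles and fixture builders used across the test files.

# G-statistic oracle: computed straight from the 2x2 contingency table via
# margins, coded independently of the package's vectorized version.
g_oracle <- function(r1, a1, r2, a2) {
  o <- matrix(c(r1, a1, r2, a2), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  s <- 0
  for (i in 1:2) for (j in 1:2) {
    if (o[i, j] > 0) s <- s + o[i, j] * log(o[i, j] / e[i, j])
  }
  2 * s
}

# Local least-squares smoother oracle: for each index, fit a polynomial of
# the given order to the centered window and evaluate it at the center.
# Interior points only (edges use asymmetric windows in the implementation).
ls_smooth_oracle <- function(y, window, order) {
  n <- length(y)
  half <- (window - 1) / 2
  out <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) {
    idx <- (i - half):(i + half)
    fit <- lm(y[idx] ~ poly(seq_along(idx), order, raw = TRUE))
    out[i] <- unname(predict(fit)[half + 1])
  }
  out
}

# Build a snp_tbl row by row for filter/swap tests.
snp_fixture <- function(..., parents = FALSE) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  roles <- if (parents)
    sample_roles("bulk1", "bulk2", parent1 = "parent1", parent2 = "parent2",
                 reference_parent = "parent1")
  else sample_roles("bulk1", "bulk2")
  attr(df, "roles") <- roles
  class(df) <- c("snp_tbl", "data.frame")
  df
}

snp_row <- function(chrom = "Chr01", pos = 100L, ref = "A", alt = "T",
                    qual = 500,
                    b1 = c("A/T", "10,10", "40"), b2 = c("A/T", "10,10", "40"),
                    p1 = NULL, p2 = NULL) {
  out <- list(CHROM = chrom, POS = as.integer(pos), QUAL = qual,
              REF = ref, ALT = alt,
              bulk1.GT = b1[1], bulk1.AD = b1[2],
              bulk1.GQ = as.integer(b1[3]),
              bulk2.GT = b2[1], bulk2.AD = b2[2],
              bulk2.GQ = as.integer(b2[3]))
  if (!is.null(p1)) {
    out$parent1.GT <- p1[1]; out$parent1.AD <- p1[2]
    out$parent1.GQ <- as.integer(p1[3])
  }
  if (!is.null(p2)) {
    out$parent2.GT <- p2[1]; out$parent2.AD <- p2[2]
    out$parent2.GQ <- as.integer(p2[3])
  }
  out
}

# Random valid allele-depth tables for property tests.
random_tables <- function(n, max_depth = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d1 <- sample(1:max_depth, n, replace = TRUE)
  d2 <- sample(1:max_depth, n, replace = TRUE)
  a1 <- vapply(d1, function(d) sample(0:d, 1L), integer(1))
  a2 <- vapply(d2, function(d) sample(0:d, 1L), integer(1))
  data.frame(r1 = d1 - a1, a1 = a1, r2 = d2 - a2, a2 = a2)
}

extdata <- function(name) {
  path <- system.file("extdata", name, package = "bsaseqr")
  if (path == "") path <- file.path("../../inst/extdata", name)
  read.delim(path, stringsAsFactors = FALSE)
}
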