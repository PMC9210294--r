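#' @importFrom stats rbinom rpois runif rnorm dhyper median quantile
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tokens treated as missing in GT/AD/GQ cells of the tabular dialect.
.missing_tokens <- c("NA", ".", "./.", ".|.", "")

.is_missing <- function(x) is.na(x) | x %in% .missing_tokens

#' Nearest-rank percentile
#'
#' The k-th order statistic with k = ceiling(p/100 * n): the percentile
#' definition used for all Monte-Carlo threshold estimates (no interpolation,
#' so thresholds are attainable values of the simulated statistic).
#'
#' @param x numeric vector.
#' @param p percentile in (0, 100).
#' @return a single value of `x`.
#' @keywords internal
q_nearest_rank <- function(x, p) {
  stopifnot(length(x) >= 1L, p > 0, p < 100)
  sort(x)[ceiling(p / 100 * length(x))]
}

# Split a vector of comma-separated AD strings into a list of integer vectors.
.split_ad <- function(x) {
  out <- vector("list", length(x))
  miss <- .is_missing(x)
  out[miss] <- list(NA_integer_)
  if (any(!miss)) {
    parts <- strsplit(x[!miss], ",", fixed = TRUE)
    out[!miss] <- lapply(parts, function(p) suppressWarnings(as.integer(p)))
  }
  out
}

# Split diploid GT strings ("G/A", "G|A") into a 2-column character matrix;
# missing calls become NA rows.
.split_gt <- function(x) {
  n <- length(x)
  m <- matrix(NA_character_, n, 2L)
  ok <- !.is_missing(x)
  if (any(ok)) {
    parts <- strsplit(x[ok], "[/|]")
    bad <- lengths(parts) != 2L
    parts[bad] <- list(c(NA_character_, NA_character_))
    m[ok, ] <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  }
  m
}

# Natural sort order for chromosome names (Chr2 before Chr10).
.chrom_order <- function(x) {
  u <- unique(x)
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", u)))
  u[order(is.na(num), num, u)]
}
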