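#' Map sample columns to analysis roles
#'
#' BSA-Seq analysis needs to know which sample column holds each bulk and,
#' optionally, each parent. The binding is always explicit; it is never
#' inferred from column order.
#'
#' @param bulk1,bulk2 sample names of the two bulks (phenotypic extremes).
#' @param parent1,parent2 optional sample names of the parental lines.
#' @param reference_parent role name (`"parent1"` or `"parent2"`) of the
#'   parent whose alleles anchor the REF position during AD/GT swapping.
#'   Defaults to `"parent1"` when parents are given.
#' @return an object of class `sample_roles`.
#' @export
#' @examples
#' sample_roles(bulk1 = "res_bulk", bulk2 = "sus_bulk",
#'              parent1 = "LD24", parent2 = "VialoneNano")
sample_roles <- function(bulk1, bulk2, parent1 = NULL, parent2 = NULL,
                         reference_parent = if (!is.null(parent1)) "parent1") {
  stopifnot(is.character(bulk1), is.character(bulk2))
  if (identical(bulk1, bulk2)) stop("bulk1 and bulk2 must name different samples")
  if (!is.null(reference_parent)) {
    if (!reference_parent %in% c("parent1", "parent2"))
      stop("reference_parent must be 'parent1' or 'parent2'")
    if (is.null(get0(reference_parent, ifnotfound = NULL)) &&
        is.null(list(parent1 = parent1, parent2 = parent2)[[reference_parent]]))
      stop("reference_parent names a parent that is not mapped")
  }
  structure(list(bulk1 = bulk1, bulk2 = bulk2,
                 parent1 = parent1, parent2 = parent2,
                 reference_parent = reference_parent),
            class = "sample_roles")
}

# Roles (in canonical order) that are mapped in a roles object.
.mapped_roles <- function(roles) {
  r <- c("bulk1", "bulk2", "parent1", "parent2")
  r[!vapply(roles[r], is.null, logical(1))]
}

.bulk_roles <- function(x) intersect(c("bulk1", "bulk2"), .tbl_roles(x))
.parent_roles <- function(x) intersect(c("parent1", "parent2"), .tbl_roles(x))

# Role names present as column prefixes in a snp_tbl.
.tbl_roles <- function(x) {
  r <- c("bulk1", "bulk2", "parent1", "parent2")
  r[paste0(r, ".GT") %in% names(x)]
}

.roles_attr <- function(x) attr(x, "roles", exact = TRUE)

.as_snp_tbl <- function(df, roles = NULL) {
  class(df) <- c("snp_tbl", "data.frame")
  if (!is.null(roles)) attr(df, "roles") <- roles
  df
}

# Locate the GT/AD/GQ column for `sample` in a raw table, accepting both the
# "sample.GT" and "sample_GT" dialects. Returns NA if absent.
.sample_col <- function(nms, sample, field) {
  cand <- c(paste0(sample, ".", field), paste0(sample, "_", field))
  hit <- cand[cand %in% nms]
  if (length(hit)) hit[1] else NA_character_
}

#' Read a SNP table in the VariantsToTable dialect
#'
#' Reads a tab-separated variant table with columns `CHROM`, `POS`, `REF`,
#' `ALT`, optionally `QUAL`, and per-sample `GT`/`AD`/`GQ` columns (either
#' `sample.GT` or `sample_GT` naming). Sample columns are renamed to their
#' analysis roles (`bulk1.GT`, ...). Missing cells (`NA`, `.`, `./.`) are kept
#' as missing, never zeroed; downstream filtering removes them explicitly.
#'
#' @param path path to the TSV file.
#' @param roles a [sample_roles()] mapping.
#' @return a `snp_tbl` data frame, rows in file order. Coordinates are 1-based.
#' @export
read_snp_table <- function(path, roles) {
  stopifnot(inherits(roles, "sample_roles"))
  if (!file.exists(path)) stop("input file not found: ", path)
  # read everything as character: AD cells like "19,9" must never be taken
  # for decimal numbers
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", dec = ".",
                           na.strings = "NA", data.table = FALSE,
                           showProgress = FALSE)
  nms <- names(raw)
  for (col in c("CHROM", "POS", "REF", "ALT")) {
    if (!col %in% nms) stop("mandatory column missing from ", path, ": ", col)
  }
  out <- data.frame(CHROM = as.character(raw$CHROM),
                    POS = as.integer(raw$POS),
                    QUAL = if ("QUAL" %in% nms) as.numeric(raw$QUAL) else NA_real_,
                    REF = as.character(raw$REF),
                    ALT = as.character(raw$ALT),
                    stringsAsFactors = FALSE)
  for (role in .mapped_roles(roles)) {
    sample <- roles[[role]]
    for (field in c("GT", "AD", "GQ")) {
      col <- .sample_col(nms, sample, field)
      if (is.na(col)) {
        # the mapped role might already be in canonical form (round trips)
        col <- .sample_col(nms, role, field)
      }
      if (is.na(col))
        stop("mandatory column missing from ", path, ": ", sample, ".", field)
      v <- raw[[col]]
      if (field == "GQ") {
        vi <- suppressWarnings(as.integer(ifelse(.is_missing(as.character(v)),
                                                 NA, as.character(v))))
        bad <- which(!is.na(v) & !.is_missing(as.character(v)) & is.na(vi))
        if (length(bad))
          stop("unparsable GQ value in column ", col, " at line ", bad[1] + 1L)
        out[[paste0(role, ".", field)]] <- vi
      } else {
        vc <- as.character(v)
        vc[.is_missing(vc)] <- NA_character_
        if (field == "AD" && any(!is.na(vc))) {
          ok <- grepl("^[0-9]+(,[0-9]+)*$", vc[!is.na(vc)])
          if (!all(ok)) {
            bad <- which(!is.na(vc))[which(!ok)[1]]
            stop("unparsable AD value in column ", col, " at line ", bad + 1L)
          }
        }
        out[[paste0(role, ".", field)]] <- vc
      }
    }
  }
  .as_snp_tbl(out, roles)
}

#' Read variants from a VCF file
#'
#' Convenience equivalent of extracting `CHROM, POS, QUAL, REF, ALT, GT, AD,
#' GQ` with GATK VariantsToTable: yields the same `snp_tbl` as
#' [read_snp_table()] on the equivalent table.
#'
#' @inheritParams read_snp_table
#' @return a `snp_tbl` data frame in file order.
#' @export
read_snp_vcf <- function(path, roles) {
  stopifnot(inherits(roles, "sample_roles"))
  if (!file.exists(path)) stop("input file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@gt) == 0L || ncol(v@gt) < 2L)
    stop("VCF has no sample columns; cannot map bulks")
  for (field in c("GT", "AD", "GQ")) {
    if (!all(grepl(paste0("(^|:)", field, "(:|$)"), v@gt[, "FORMAT"])))
      stop("FORMAT field absent from VCF: ", field)
  }
  fix <- vcfR::getFIX(v)
  samples <- colnames(v@gt)[-1]
  out <- data.frame(CHROM = fix[, "CHROM"],
                    POS = as.integer(fix[, "POS"]),
                    QUAL = suppressWarnings(as.numeric(fix[, "QUAL"])),
                    REF = fix[, "REF"],
                    ALT = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT", return.alleles = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  gq <- vcfR::extract.gt(v, element = "GQ")
  for (role in .mapped_roles(roles)) {
    sample <- roles[[role]]
    if (!sample %in% samples)
      stop("sample not present in VCF: ", sample)
    g <- gt[, sample]
    g[.is_missing(g)] <- NA_character_
    a <- ad[, sample]
    a[.is_missing(a)] <- NA_character_
    q <- suppressWarnings(as.integer(gq[, sample]))
    out[[paste0(role, ".GT")]] <- unname(g)
    out[[paste0(role, ".AD")]] <- unname(a)
    out[[paste0(role, ".GQ")]] <- unname(q)
  }
  rownames(out) <- NULL
  .as_snp_tbl(out, roles)
}

#' Write a SNP table
#'
#' Writes a `snp_tbl` (optionally carrying appended statistic columns) as a
#' tab-separated file in the same dialect read by [read_snp_table()].
#' Round-trip property: reading the written file with the same roles
#' reproduces the table field-for-field.
#'
#' @param x a `snp_tbl` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  data.table::fwrite(as.data.frame(x), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}
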