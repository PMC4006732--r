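ASSAY_LEVELS <- c("rna_seq", "mmpcr", "exome_dna")
VARIANT_CLASS_LEVELS <- c("control", "deleterious_nsSNP", "nonsense")
ASE_CLASS_LEVELS <- c("NO_ASE", "SHARED_ASE", "VARIABLE_ASE", "UNCLASSIFIED")
FILTER_FLAGS <- c("BASE_QUALITY", "ALLELE_DEPTH", "TOTAL_DEPTH",
                  "SIGNIFICANCE", "BIALLELIC", "INTRAGENIC")

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Validate a table of heterozygous sites
#'
#' Checks the site table invariants: required columns, 1-based positions,
#' distinct single-nucleotide alleles, known variant classes, minor allele
#' frequencies in \[0, 1\] (NA allowed) and unique `site_id`s.
#'
#' @param sites A data frame of heterozygous sites.
#' @return The input, invisibly, as a tibble.
#' @export
validate_sites <- function(sites) {
  sites <- tibble::as_tibble(sites)
  require_columns(sites, c("site_id", "chrom", "pos", "ref_base", "alt_base"),
                  "site table")
  if (anyDuplicated(sites$site_id)) abort("duplicate site_id in site table")
  if (any(sites$pos < 1)) abort("site positions must be >= 1 (1-based)")
  bad <- sites$ref_base == sites$alt_base |
    !sites$ref_base %in% c("A", "C", "G", "T") |
    !sites$alt_base %in% c("A", "C", "G", "T")
  if (any(bad)) {
    abort(sprintf("invalid alleles for site(s): %s",
                  paste(head(sites$site_id[bad], 5), collapse = ", ")))
  }
  if ("variant_class" %in% names(sites) &&
      !all(sites$variant_class %in% VARIANT_CLASS_LEVELS)) {
    abort("variant_class must be one of: control, deleterious_nsSNP, nonsense")
  }
  if ("maf" %in% names(sites)) {
    m <- sites$maf[!is.na(sites$maf)]
    if (any(m < 0 | m > 1)) abort("maf must lie in [0, 1]")
  }
  invisible(sites)
}

#' Validate a table of allelic read counts
#'
#' Checks the count-record invariants: required key and count columns,
#' non-negative integer counts, known assay labels, and uniqueness on
#' (site_id, tissue_id, replicate_id, assay).
#'
#' @param counts A data frame of allele-count records.
#' @return The input, invisibly, as a tibble.
#' @export
validate_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  require_columns(counts,
                  c("site_id", "tissue_id", "replicate_id", "assay",
                    "ref_count", "alt_count", "other_count"),
                  "count table")
  if (!all(counts$assay %in% ASSAY_LEVELS)) {
    abort(sprintf("assay must be one of: %s",
                  paste(ASSAY_LEVELS, collapse = ", ")))
  }
  cnt <- c(counts$ref_count, counts$alt_count, counts$other_count)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt))) {
    abort("counts must be non-negative integers")
  }
  key <- paste(counts$site_id, counts$tissue_id, counts$replicate_id,
               counts$assay, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- counts[duplicated(key), , drop = FALSE]
    abort(sprintf(
      "duplicate (site, tissue, replicate, assay) record(s), e.g. %s/%s/%s/%s",
      dup$site_id[1], dup$tissue_id[1], dup$replicate_id[1], dup$assay[1]))
  }
  invisible(counts)
}
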