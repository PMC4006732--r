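#' Read or write allele-count tables as TSV
#'
#' Tab-separated serialisation of allele-count records with the fixed
#' header `site_id, tissue_id, replicate_id, assay, ref_count, alt_count,
#' other_count`. Write-then-read is the identity, bit-exact on the integer
#' count fields. A missing `other_count` column is tolerated on read and
#' defaults to 0 with a warning; negative counts or duplicate
#' (site, tissue, replicate, assay) keys are validation errors.
#'
#' @param path File path.
#' @param counts A tibble of allele-count records.
#' @return `read_count_table()` returns the count tibble;
#'   `write_count_table()` returns `counts` invisibly.
#' @export
read_count_table <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              site_id = readr::col_character(),
                              tissue_id = readr::col_character(),
                              replicate_id = readr::col_character(),
                              assay = readr::col_character(),
                              .default = readr::col_integer()
                            ))
  require_columns(counts, c("site_id", "tissue_id", "replicate_id", "assay",
                            "ref_count", "alt_count"), "count table")
  if (!"other_count" %in% names(counts)) {
    warn("count table has no other_count column; defaulting to 0")
    counts$other_count <- 0L
  }
  validate_counts(counts)
  counts
}

#' @rdname read_count_table
#' @export
write_count_table <- function(counts, path) {
  validate_counts(counts)
  readr::write_tsv(counts, path)
  invisible(counts)
}

#' Write or read ASE calls as TSV
#'
#' One row per call with all fields; the set of raised filter flags is
#' serialised as a semicolon-joined list in a `filter_flags` column (empty
#' string when no flag is raised) alongside the per-flag logical columns.
#'
#' @param calls A tibble of ASE calls from [call_ase()].
#' @param path File path.
#' @return `write_ase_table()` returns `calls` invisibly;
#'   `read_ase_table()` returns the call tibble.
#' @export
write_ase_table <- function(calls, path) {
  flag_cols <- paste0("flag_", tolower(FILTER_FLAGS))
  require_columns(calls, c("site_id", "tissue_id", "assay", "ref_count",
                           "alt_count", "allelic_ratio", "p_value",
                           "qc_pass", "is_ase", flag_cols), "ASE call table")
  out <- calls
  flags <- as.matrix(calls[flag_cols])
  out$filter_flags <- apply(flags, 1, function(row)
    paste(FILTER_FLAGS[row], collapse = ";"))
  readr::write_tsv(out, path)
  invisible(calls)
}

#' @rdname write_ase_table
#' @export
read_ase_table <- function(path) {
  calls <- readr::read_tsv(path, show_col_types = FALSE)
  calls$filter_flags <- NULL
  tibble::as_tibble(calls)
}
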