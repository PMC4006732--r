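#' Convert samtools-mpileup text to allele counts at known het sites
#'
#' Parses 6-column mpileup text (chrom, pos, ref, depth, read bases, base
#' qualities) and tallies, for each known heterozygous site, the reads
#' supporting the reference allele, the alternate allele, and any other
#' base, after discarding bases below a base-quality threshold. The base
#' string is decoded per the mpileup grammar: `.`/`,` are the reference
#' base, letters are explicit bases (case gives strand, which is ignored),
#' `^X` and `$` are read start/end markers, `+n`/`-n` introduce indel
#' sequences (skipped), `*` marks a deleted base (tallied as other), and
#' `>`/`<` are reference skips (excluded). Pileup lines for positions not
#' in `sites` are ignored; a pileup reference base that contradicts the
#' site's reference allele is an error.
#'
#' @param mpileup A path to an mpileup text file, or a character vector of
#'   mpileup lines.
#' @param sites A site tibble (see [read_het_sites()]).
#' @param min_base_quality Minimum Phred base quality; bases below it are
#'   excluded from all counts (default 10).
#' @param tissue_id,replicate_id,assay Labels stamped on the returned
#'   records.
#' @return A tibble of allele-count records (one row per covered site) with
#'   columns `site_id`, `tissue_id`, `replicate_id`, `assay`, `ref_count`,
#'   `alt_count`, `other_count`.
#' @export
pileup_to_counts <- function(mpileup, sites, min_base_quality = 10,
                             tissue_id = "sample", replicate_id = "r1",
                             assay = "rna_seq") {
  sites <- validate_sites(sites)
  stopifnot(min_base_quality >= 0, assay %in% ASSAY_LEVELS)
  lines <- if (length(mpileup) == 1 && !grepl("\n", mpileup) &&
               file.exists(mpileup)) readLines(mpileup) else
    unlist(strsplit(mpileup, "\n", fixed = TRUE))
  lines <- lines[nzchar(lines)]

  site_key <- paste(sites$chrom, sites$pos)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) abort(sprintf("malformed mpileup line %d: %d field(s)", i, length(f)))
    idx <- match(paste(f[1], f[2]), site_key)
    if (is.na(idx)) next
    site <- sites[idx, ]
    if (toupper(f[3]) != site$ref_base) {
      abort(sprintf("pileup reference base '%s' contradicts site %s (ref %s)",
                    f[3], site$site_id, site$ref_base))
    }
    calls <- decode_pileup_bases(f[5], site$ref_base)
    quals <- utf8ToInt(f[6]) - 33L
    if (length(calls) != length(quals)) {
      abort(sprintf("mpileup line %d: %d base call(s) but %d quality character(s)",
                    i, length(calls), length(quals)))
    }
    calls <- calls[quals >= min_base_quality]
    calls <- calls[!is.na(calls)]      # reference skips carry no base call
    out[[i]] <- tibble::tibble(
      site_id = site$site_id,
      tissue_id = tissue_id, replicate_id = replicate_id, assay = assay,
      ref_count = sum(calls == site$ref_base),
      alt_count = sum(calls == site$alt_base),
      other_count = sum(!calls %in% c(site$ref_base, site$alt_base))
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(site_id = character(), tissue_id = character(),
                          replicate_id = character(), assay = character(),
                          ref_count = integer(), alt_count = integer(),
                          other_count = integer())
  }
  validate_counts(res)
  res
}

# One uppercase base per sequenced read, in pileup order; '*' (deleted base)
# is kept as a non-allele call so its quality character stays aligned;
# '>'/'<' reference skips are kept for alignment and dropped by the caller
# via their base value never matching A/C/G/T... they must be EXCLUDED with
# their quality, so they are returned as NA and filtered after quality
# pairing.
decode_pileup_bases <- function(bases, ref_base) {
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  calls <- character(0)
  i <- 1L
  n <- length(ch)
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "^") {
      i <- i + 2L                      # caret + mapping-quality char
    } else if (c0 == "$") {
      i <- i + 1L
    } else if (c0 %in% c("+", "-")) {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", ch[j])) j <- j + 1L
      len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len                     # skip the inserted/deleted sequence
    } else if (c0 %in% c(".", ",")) {
      calls <- c(calls, ref_base); i <- i + 1L
    } else if (c0 %in% c(">", "<")) {
      calls <- c(calls, NA_character_); i <- i + 1L
    } else {
      calls <- c(calls, toupper(c0)); i <- i + 1L
    }
  }
  calls
}
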