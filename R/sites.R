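#' Read high-confidence heterozygous sites from a VCF
#'
#' Parses a VCF with one or more DNA-sample genotype columns and keeps only
#' bi-allelic SNPs called heterozygous in every sample present — the
#' genotype-concordance rule that defines high-confidence sites for ASE
#' analysis. Multi-allelic records, indels, and sites with missing or
#' non-concordant genotypes are skipped (multi-allelic/indel records with a
#' warning). An optional annotation table supplies the variant class, minor
#' allele frequency and privacy flag, joined on (chrom, pos, ref, alt);
#' annotation rows that match no VCF site are skipped with a warning.
#'
#' @param vcf_path Path to a VCF (v4.x) with genotype columns.
#' @param annotation_table_path Optional path to a tab-separated annotation
#'   table with columns `chrom`, `pos`, `ref_base`, `alt_base` and any of
#'   `variant_class`, `maf`, `is_private`, `gene_id`, `is_intragenic`.
#' @return A tibble of heterozygous sites with columns `site_id`, `chrom`,
#'   `pos`, `ref_base`, `alt_base`, `gene_id`, `variant_class`, `maf`,
#'   `is_private`, `is_intragenic`.
#' @export
read_het_sites <- function(vcf_path, annotation_table_path = NULL) {
  lines <- readLines(vcf_path)
  body <- which(!startsWith(lines, "#"))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 10)) {
    abort(sprintf("malformed VCF line %d: expected at least 10 tab-separated fields (genotypes required)",
                  body[which(nfield < 10)[1]]))
  }

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  gt <- vcfR::extract.gt(vcf, element = "GT")

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 & !multi
  if (any(multi)) {
    warn(sprintf("skipping %d multi-allelic VCF record(s)", sum(multi)))
  }
  if (any(!snp & !multi)) {
    warn(sprintf("skipping %d non-SNP VCF record(s)", sum(!snp & !multi)))
  }

  het <- c("0/1", "1/0", "0|1", "1|0")
  all_het <- apply(gt, 1, function(g) all(!is.na(g) & g %in% het))
  keep <- snp & all_het

  sites <- tibble::tibble(
    site_id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                     paste(fix$CHROM[keep], fix$POS[keep],
                           fix$REF[keep], fix$ALT[keep], sep = "_"),
                     fix$ID[keep]),
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref_base = fix$REF[keep],
    alt_base = fix$ALT[keep],
    gene_id = NA_character_,
    variant_class = "control",
    maf = NA_real_,
    is_private = FALSE,
    is_intragenic = TRUE
  )

  if (!is.null(annotation_table_path)) {
    ann <- readr::read_tsv(annotation_table_path, show_col_types = FALSE)
    require_columns(ann, c("chrom", "pos", "ref_base", "alt_base"),
                    "annotation table")
    key_site <- paste(sites$chrom, sites$pos, sites$ref_base, sites$alt_base)
    key_ann <- paste(ann$chrom, ann$pos, ann$ref_base, ann$alt_base)
    unknown <- !key_ann %in% key_site
    if (any(unknown)) {
      warn(sprintf("skipping %d annotation row(s) for sites absent from the VCF",
                   sum(unknown)))
      ann <- ann[!unknown, , drop = FALSE]
      key_ann <- key_ann[!unknown]
    }
    idx <- match(key_site, key_ann)
    for (col in intersect(c("gene_id", "variant_class", "maf", "is_private",
                            "is_intragenic"), names(ann))) {
      hit <- !is.na(idx)
      sites[[col]][hit] <- ann[[col]][idx[hit]]
    }
  }

  validate_sites(sites)
  sites
}

#' Flag sites that fall inside annotated gene intervals
#'
#' Reads a BED file of gene intervals (0-based half-open, as BED requires;
#' the reader performs the 1-based conversion) and sets each site's
#' `is_intragenic` flag by interval overlap. When the BED has a name column
#' and a site has no `gene_id` yet, the first overlapping interval's name is
#' recorded.
#'
#' @param sites A site tibble (see [read_het_sites()]).
#' @param bed_path Path to a BED3+ file of gene intervals.
#' @return `sites` with `is_intragenic` (and possibly `gene_id`) updated.
#' @export
annotate_intragenic <- function(sites, bed_path) {
  sites <- validate_sites(sites)
  genes <- rtracklayer::import(bed_path, format = "BED")
  pts <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::findOverlaps(pts, genes)
  sites$is_intragenic <- seq_len(nrow(sites)) %in% S4Vectors::queryHits(hits)
  nm <- genes$name
  if (!is.null(nm)) {
    if (!"gene_id" %in% names(sites)) sites$gene_id <- NA_character_
    first <- !duplicated(S4Vectors::queryHits(hits))
    q <- S4Vectors::queryHits(hits)[first]
    s <- S4Vectors::subjectHits(hits)[first]
    fill <- is.na(sites$gene_id[q])
    sites$gene_id[q[fill]] <- nm[s[fill]]
  }
  sites
}

#' Read or write a site table as TSV
#'
#' Plain tab-separated serialisation of the site tibble; `write` then `read`
#' is the identity on all fields.
#'
#' @param path File path.
#' @param sites A site tibble.
#' @return `read_site_table()` returns the site tibble;
#'   `write_site_table()` returns `sites` invisibly.
#' @export
read_site_table <- function(path) {
  sites <- readr::read_tsv(
    path,
    col_types = readr::cols(
      site_id = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      ref_base = readr::col_character(),
      alt_base = readr::col_character(),
      gene_id = readr::col_character(),
      variant_class = readr::col_character(),
      maf = readr::col_double(),
      is_private = readr::col_logical(),
      is_intragenic = readr::col_logical()
    )
  )
  validate_sites(sites)
  sites
}

#' @rdname read_site_table
#' @export
write_site_table <- function(sites, path) {
  validate_sites(sites)
  readr::write_tsv(sites, path)
  invisible(sites)
}
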