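# in-code fixtures shared across test files

make_sites <- function(n = 3, intragenic = TRUE) {
  tibble::tibble(
    site_id = sprintf("S%03d", seq_len(n)),
    chrom = "chr1",
    pos = 100L * seq_len(n),
    ref_base = rep(c("C", "A", "G"), length.out = n),
    alt_base = rep(c("T", "G", "A"), length.out = n),
    gene_id = sprintf("G%03d", seq_len(n)),
    variant_class = "control",
    maf = 0.2,
    is_private = FALSE,
    is_intragenic = intragenic
  )
}

make_counts <- function(ref, alt, other = 0, site_id = NULL,
                        tissue_id = "liver", replicate_id = "r1",
                        assay = "mmpcr") {
  n <- length(ref)
  tibble::tibble(
    site_id = site_id %||% sprintf("S%03d", seq_len(n)),
    tissue_id = tissue_id,
    replicate_id = replicate_id,
    assay = assay,
    ref_count = as.integer(ref),
    alt_count = as.integer(alt),
    other_count = as.integer(rep(other, length.out = n))
  )
}

flat_bias <- function(p = 0.5, tissue = NULL, assay = NULL) {
  b <- tibble::tibble(tissue_id = tissue %||% NA_character_,
                      assay = assay %||% NA_character_,
                      p_ref_hat = p, n_records = NA_integer_,
                      n_reads = NA_integer_)
  class(b) <- c("ase_bias", class(b))
  attr(b, "scope") <- if (is.null(tissue)) "global" else "sample"
  b
}

# profile tibble built directly from per-tissue ratios / p-values
make_profile <- function(ratios, p_values = NULL, site_id = "S001") {
  tissues <- paste0("t", seq_along(ratios))
  p_values <- p_values %||% rep(1, length(ratios))
  m <- mean(ratios)
  s <- sqrt(mean((ratios - m)^2))
  nt <- length(ratios)
  prof <- tibble::tibble(
    site_id = site_id,
    ratios = list(stats::setNames(ratios, tissues)),
    p_values = list(stats::setNames(p_values, tissues)),
    n_tissues = nt,
    mean_ratio = m,
    ratio_dispersion = s,
    class_label = "UNCLASSIFIED"
  )
  class(prof) <- c("ase_profiles", class(prof))
  prof
}

`%||%` <- function(x, y) if (is.null(x)) y else x
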