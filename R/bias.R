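#' Estimate the reference-mapping bias from allele counts
#'
#' Reads carrying the reference allele align to the reference genome
#' slightly more often than reads carrying the alternate allele, so under
#' no ASE the expected reference fraction at a heterozygous site exceeds
#' 0.5. The ASE test corrects for this by replacing 0.5 with the empirical
#' probability that a read carries the reference allele, pooled over all
#' sites: `p_ref_hat = sum(ref) / sum(ref + alt)` over records passing the
#' depth filters. Only depth filters are applied before pooling —
#' significance must not feed back into the null.
#'
#' The estimate is computed per sample (tissue x assay, the default, since
#' mapping-bias distributions differ between libraries) or globally, and
#' clamped to `[1e-6, 1 - 1e-6]`.
#'
#' @param counts A tibble of allele-count records.
#' @param scope `"sample"` for one estimate per (tissue_id, assay) or
#'   `"global"` for a single pooled estimate.
#' @param params A [filter_params()] object supplying the depth filters.
#' @return A tibble of class `ase_bias` with columns `tissue_id`, `assay`
#'   (both `NA` under global scope), `p_ref_hat`, `n_records`, `n_reads`.
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   site_id = c("s1", "s2"), tissue_id = "liver", replicate_id = "r1",
#'   assay = "rna_seq", ref_count = c(60L, 54L), alt_count = c(40L, 46L),
#'   other_count = 0L
#' )
#' estimate_reference_bias(counts, scope = "global")
estimate_reference_bias <- function(counts, scope = c("sample", "global"),
                                    params = filter_params()) {
  scope <- match.arg(scope)
  counts <- validate_counts(counts)
  params <- as_filter_params(params)

  passing <- dplyr::filter(
    counts,
    .data$ref_count >= params$min_allele_depth,
    .data$alt_count >= params$min_allele_depth,
    .data$ref_count + .data$alt_count >= params$min_total_depth
  )
  if (nrow(passing) == 0) {
    abort("insufficient data for bias estimation: no records pass the depth filters")
  }

  grouped <- if (scope == "sample") {
    dplyr::group_by(passing, .data$tissue_id, .data$assay)
  } else {
    dplyr::group_by(dplyr::mutate(passing, tissue_id = NA_character_,
                                  assay = NA_character_),
                    .data$tissue_id, .data$assay)
  }
  bias <- dplyr::summarise(
    grouped,
    p_ref_hat = pmin(pmax(sum(.data$ref_count) /
                            sum(.data$ref_count + .data$alt_count),
                          1e-6), 1 - 1e-6),
    n_records = dplyr::n(),
    n_reads = sum(.data$ref_count + .data$alt_count),
    .groups = "drop"
  )
  class(bias) <- c("ase_bias", class(bias))
  attr(bias, "scope") <- scope
  bias
}

#' @exportS3Method tidy ase_bias
tidy.ase_bias <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method glance ase_bias
glance.ase_bias <- function(x, ...) {
  tibble::tibble(
    scope = attr(x, "scope"),
    n_groups = nrow(x),
    mean_p_ref_hat = mean(x$p_ref_hat),
    min_p_ref_hat = min(x$p_ref_hat),
    max_p_ref_hat = max(x$p_ref_hat)
  )
}

# p_ref_hat for one (tissue, assay) pair, honouring the bias model's scope
lookup_bias <- function(bias, tissue_id, assay) {
  if (identical(attr(bias, "scope"), "global")) {
    return(rep(bias$p_ref_hat[1], length(tissue_id)))
  }
  idx <- match(paste(tissue_id, assay), paste(bias$tissue_id, bias$assay))
  if (anyNA(idx)) {
    missing <- unique(paste0(tissue_id, "/", assay)[is.na(idx)])
    abort(sprintf("no bias estimate for sample(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bias$p_ref_hat[idx]
}
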