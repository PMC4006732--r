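#' Call allele-specific expression per site per tissue
#'
#' Applies the QC filter cascade to one assay's allele-count records and
#' runs the bias-corrected exact binomial test on every record. Flags:
#'
#' * `ALLELE_DEPTH` — either allele seen fewer than `min_allele_depth` times;
#' * `TOTAL_DEPTH` — ref + alt below `min_total_depth`;
#' * `BIALLELIC` — reads supporting a third/fourth base exceed
#'   `max_other_fraction` of all reads;
#' * `INTRAGENIC` — site outside annotated genes (when `require_intragenic`);
#' * `SIGNIFICANCE` — binomial p-value at or above the assay's alpha.
#'
#' (`BASE_QUALITY` is applied upstream in [pileup_to_counts()] and never
#' raised here.) A call passes QC iff none of the depth/bi-allelic/
#' intragenic flags is raised; it is an ASE call iff it passes QC and its
#' p-value is below the assay-specific alpha. The allelic ratio is
#' `alt / (ref + alt)`, the alternate-allele fraction.
#'
#' @param counts Allele-count records from a single assay (replicates
#'   already merged; see [merge_replicates()]).
#' @param sites Site tibble; every record's `site_id` must appear here.
#' @param bias An `ase_bias` model from [estimate_reference_bias()].
#' @param params A [filter_params()] object.
#' @return A tibble of class `ase_calls`: one row per record with counts,
#'   `allelic_ratio`, `p_value`, one logical `flag_*` column per filter,
#'   `qc_pass` and `is_ase`.
#' @export
call_ase <- function(counts, sites, bias, params = filter_params()) {
  counts <- validate_counts(counts)
  sites <- validate_sites(sites)
  params <- as_filter_params(params)
  if (length(unique(counts$assay)) > 1) {
    abort("call_ase expects records from a single assay; split by assay first")
  }
  unknown <- setdiff(counts$site_id, sites$site_id)
  if (length(unknown) > 0) {
    abort(sprintf("count record(s) for unknown site id(s): %s",
                  paste(head(unknown, 10), collapse = ", ")))
  }

  site_idx <- match(counts$site_id, sites$site_id)
  total <- counts$ref_count + counts$alt_count
  grand <- total + counts$other_count
  alpha <- alpha_for_assay(params, counts$assay)

  calls <- dplyr::mutate(
    counts,
    allelic_ratio = ifelse(total > 0, .data$alt_count / total, NA_real_),
    p_ref_hat = lookup_bias(bias, .data$tissue_id, .data$assay),
    p_value = safe_binom_p(.data$ref_count, .data$alt_count, .data$p_ref_hat),
    flag_base_quality = FALSE,
    flag_allele_depth = .data$ref_count < params$min_allele_depth |
      .data$alt_count < params$min_allele_depth,
    flag_total_depth = total < params$min_total_depth,
    flag_significance = is.na(.data$p_value) | .data$p_value >= alpha,
    flag_biallelic = grand > 0 &
      .data$other_count / grand > params$max_other_fraction,
    flag_intragenic = params$require_intragenic &
      !sites$is_intragenic[site_idx],
    qc_pass = !(.data$flag_allele_depth | .data$flag_total_depth |
                  .data$flag_biallelic | .data$flag_intragenic),
    is_ase = .data$qc_pass & !.data$flag_significance
  )
  class(calls) <- c("ase_calls", class(calls))
  calls
}

# binomial p for covered records, NA where ref + alt == 0
safe_binom_p <- function(ref_count, alt_count, p_ref_hat) {
  p <- rep(NA_real_, length(ref_count))
  ok <- ref_count + alt_count >= 1
  if (any(ok)) {
    p[ok] <- binomial_ase_test(ref_count[ok], alt_count[ok], p_ref_hat[ok])
  }
  p
}
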