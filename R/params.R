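#' Quality-control filter parameters for ASE calling
#'
#' Thresholds applied by [call_ase()] and, for the depth filters, by
#' [estimate_reference_bias()]. Defaults follow the standard cascade for
#' per-site allelic read counts: each allele must be seen at least 5 times,
#' the two alleles together at least 20 times, reads supporting a third or
#' fourth base may make up at most 5% of all reads at the site, and the
#' site must fall inside an annotated gene. Significance cutoffs differ by
#' assay because targeted mmPCR-seq reaches far greater depth than RNA-seq
#' (alpha 0.01 vs 0.05). A stricter "total depth 10, no per-allele floor"
#' variant can be configured via `min_allele_depth = 0` and
#' `min_total_depth = 10`.
#'
#' @param min_allele_depth Minimum reads per allele (default 5).
#' @param min_total_depth Minimum ref + alt reads (default 20).
#' @param alpha_rna Significance cutoff for RNA-seq calls (default 0.05).
#' @param alpha_mmpcr Significance cutoff for mmPCR-seq calls (default 0.01).
#' @param max_other_fraction Maximum fraction of reads supporting a base
#'   other than the two expected alleles (default 0.05); operationalises the
#'   bi-allelic-expression filter.
#' @param require_intragenic Flag sites outside annotated genes (default TRUE).
#' @return A list of class `filter_params`.
#' @export
#' @examples
#' filter_params(min_total_depth = 10)
filter_params <- function(min_allele_depth = 5,
                          min_total_depth = 20,
                          alpha_rna = 0.05,
                          alpha_mmpcr = 0.01,
                          max_other_fraction = 0.05,
                          require_intragenic = TRUE) {
  stopifnot(
    min_allele_depth >= 0, min_total_depth >= 0,
    alpha_rna > 0, alpha_rna < 1,
    alpha_mmpcr > 0, alpha_mmpcr < 1,
    max_other_fraction >= 0, max_other_fraction <= 1,
    is.logical(require_intragenic), length(require_intragenic) == 1
  )
  structure(
    list(
      min_allele_depth = min_allele_depth,
      min_total_depth = min_total_depth,
      alpha_rna = alpha_rna,
      alpha_mmpcr = alpha_mmpcr,
      max_other_fraction = max_other_fraction,
      require_intragenic = require_intragenic
    ),
    class = "filter_params"
  )
}

#' Cross-tissue ASE classification parameters
#'
#' Cutoffs used by [classify_profiles()] to partition sites into no ASE,
#' shared ASE and variable ASE from the mean and dispersion (population
#' standard deviation) of allelic ratios across tissues. A site is balanced
#' when its mean ratio lies strictly inside (`ratio_lo`, `ratio_hi`);
#' cross-tissue variability is low when the dispersion is strictly below
#' `dispersion_max`. Shared and variable ASE additionally require at least
#' `min_significant_tissues` tissues with a binomial p-value below `alpha`.
#' Boundary ties (exact equality with any cutoff) are left unclassified, as
#' are profiles observed in fewer than `min_tissues` tissues.
#'
#' @param ratio_lo,ratio_hi Balanced-band bounds on the mean allelic ratio
#'   (defaults 0.35 and 0.65, i.e. 0.5 +/- 0.15).
#' @param dispersion_max Cutoff on the cross-tissue standard deviation of
#'   allelic ratios (default 0.2).
#' @param alpha Per-tissue significance cutoff (default 0.01).
#' @param min_tissues Minimum qc-passing tissues for classification
#'   (default 3).
#' @param min_significant_tissues Minimum significant tissues required for
#'   an ASE label (default 1).
#' @return A list of class `class_params`.
#' @export
class_params <- function(ratio_lo = 0.35,
                         ratio_hi = 0.65,
                         dispersion_max = 0.2,
                         alpha = 0.01,
                         min_tissues = 3,
                         min_significant_tissues = 1) {
  stopifnot(
    ratio_lo > 0, ratio_lo < 0.5, ratio_hi > 0.5, ratio_hi < 1,
    dispersion_max > 0,
    alpha > 0, alpha < 1,
    min_tissues >= 1, min_significant_tissues >= 0
  )
  structure(
    list(
      ratio_lo = ratio_lo,
      ratio_hi = ratio_hi,
      dispersion_max = dispersion_max,
      alpha = alpha,
      min_tissues = min_tissues,
      min_significant_tissues = min_significant_tissues
    ),
    class = "class_params"
  )
}

as_filter_params <- function(x) {
  if (inherits(x, "filter_params")) return(x)
  do.call(filter_params, as.list(x))
}

as_class_params <- function(x) {
  if (inherits(x, "class_params")) return(x)
  do.call(class_params, as.list(x))
}

alpha_for_assay <- function(params, assay) {
  ifelse(assay == "mmpcr", params$alpha_mmpcr, params$alpha_rna)
}
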