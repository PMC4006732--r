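#' Merge technical replicates by summing read counts
#'
#' Sums ref/alt/other counts over replicates of the same
#' (site, tissue, assay); the merged record's `replicate_id` is
#' `"merged"`. Read totals are conserved, and the binomial ASE test on a
#' merged record equals the test on the summed counts by definition.
#'
#' @param counts Allele-count records.
#' @return One merged record per (site_id, tissue_id, assay).
#' @export
merge_replicates <- function(counts) {
  counts <- validate_counts(counts)
  mixed <- counts |>
    dplyr::distinct(.data$site_id, .data$tissue_id, .data$replicate_id,
                    .data$assay) |>
    dplyr::count(.data$site_id, .data$tissue_id, .data$replicate_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(mixed) > 0) {
    abort(sprintf("mixed assays under one (site, tissue, replicate) key, e.g. %s/%s",
                  mixed$site_id[1], mixed$tissue_id[1]))
  }
  counts |>
    dplyr::group_by(.data$site_id, .data$tissue_id, .data$assay) |>
    dplyr::summarise(
      replicate_id = "merged",
      ref_count = sum(.data$ref_count),
      alt_count = sum(.data$alt_count),
      other_count = sum(.data$other_count),
      .groups = "drop"
    ) |>
    dplyr::relocate("replicate_id", .after = "tissue_id")
}

#' Concordance of allelic ratios between technical replicates
#'
#' Matches QC-passing calls of two replicates on (site, tissue) and
#' reports, per tissue, the Pearson correlation of allelic ratios over
#' shared sites and the mean absolute ratio difference stratified by read
#' depth (binned by the smaller of the two replicate depths). Tissues with
#' fewer than 3 shared sites get a missing correlation with a warning.
#'
#' @param calls_rep1,calls_rep2 `ase_calls` tibbles for the two replicates.
#' @param depth_breaks Left edges of the depth bins; the last bin is
#'   open-ended (default `c(20, 100, 200, 500, 2000)`).
#' @return A tibble of class `ase_concordance`: per tissue, `pearson_r`,
#'   `n_sites`, and a nested `by_depth` tibble of `mean_abs_delta` per bin.
#' @export
replicate_concordance <- function(calls_rep1, calls_rep2,
                                  depth_breaks = c(20, 100, 200, 500, 2000)) {
  pair <- match_replicate_calls(calls_rep1, calls_rep2)
  breaks <- c(depth_breaks, Inf)
  labels <- paste0("[", depth_breaks, ",",
                   c(depth_breaks[-1], "Inf"), ")")

  rep <- pair |>
    dplyr::mutate(
      min_depth = pmin(.data$total.r1, .data$total.r2),
      depth_bin = cut(.data$min_depth, breaks = breaks, labels = labels,
                      right = FALSE)
    ) |>
    dplyr::group_by(.data$tissue_id) |>
    dplyr::group_modify(function(d, key) {
      tibble::tibble(
        n_sites = nrow(d),
        pearson_r = if (nrow(d) >= 3)
          cor(d$ratio.r1, d$ratio.r2, method = "pearson") else NA_real_,
        by_depth = list(
          tibble::tibble(depth_bin = d$depth_bin,
                         abs_delta = abs(d$ratio.r1 - d$ratio.r2)) |>
            dplyr::group_by(.data$depth_bin, .drop = FALSE) |>
            dplyr::summarise(mean_abs_delta = mean(.data$abs_delta),
                             n = dplyr::n(), .groups = "drop")
        )
      )
    }) |>
    dplyr::ungroup()
  low <- rep$tissue_id[rep$n_sites < 3]
  if (length(low) > 0) {
    warn(sprintf("fewer than 3 shared sites for tissue(s) %s; correlation missing",
                 paste(low, collapse = ", ")))
  }
  class(rep) <- c("ase_concordance", class(rep))
  rep
}

match_replicate_calls <- function(calls_rep1, calls_rep2) {
  pick <- function(calls, tag) {
    require_columns(calls, c("site_id", "tissue_id", "allelic_ratio",
                             "qc_pass", "ref_count", "alt_count"),
                    "replicate call table")
    calls |>
      dplyr::filter(.data$qc_pass, !is.na(.data$allelic_ratio)) |>
      dplyr::transmute(.data$site_id, .data$tissue_id,
                       "ratio.{tag}" := .data$allelic_ratio,
                       "p.{tag}" := .data$p_value,
                       "total.{tag}" := .data$ref_count + .data$alt_count)
  }
  dplyr::inner_join(pick(calls_rep1, "r1"), pick(calls_rep2, "r2"),
                    by = c("site_id", "tissue_id"))
}

#' Classification-reproducibility sweep over cutoff grids
#'
#' Classifies cross-tissue profiles independently from each technical
#' replicate at every grid point (balanced-band ratio cutoff pair x
#' dispersion cutoff), optionally after dropping listed tissues, and
#' reports the fraction of sites receiving identical labels: over the
#' three classes (no/shared/variable ASE) and over the binary coarsening
#' (ASE = shared or variable, versus no ASE). Sites unclassified in either
#' replicate at a grid point are excluded from that point's denominator.
#'
#' @param calls_rep1,calls_rep2 `ase_calls` tibbles for the two replicates
#'   (single assay, per-replicate calls).
#' @param ratio_cutoffs List of `c(lo, hi)` balanced-band pairs
#'   (default the two standard bands `0.4–0.6` and `0.35–0.65`).
#' @param dispersion_cutoffs Numeric vector of dispersion cutoffs
#'   (default 8 values spanning 0.05–0.3).
#' @param exclusions Character vector of tissue_ids to drop before
#'   classification (default none).
#' @param params Base [class_params()]; the grid overrides its band and
#'   dispersion entries.
#' @return A tibble of class `ase_sweep`: one row per grid point with
#'   `ratio_lo`, `ratio_hi`, `dispersion_cutoff`, `excluded_tissues`,
#'   `n_sites`, `concordance_3class`, `concordance_2class`.
#' @export
classification_sweep <- function(calls_rep1, calls_rep2,
                                 ratio_cutoffs = list(c(0.4, 0.6),
                                                      c(0.35, 0.65)),
                                 dispersion_cutoffs = seq(0.05, 0.3,
                                                          length.out = 8),
                                 exclusions = character(0),
                                 params = class_params()) {
  if (length(ratio_cutoffs) == 0 || length(dispersion_cutoffs) == 0) {
    abort("empty cutoff grid")
  }
  params <- as_class_params(params)
  drop_tissues <- function(calls)
    dplyr::filter(calls, !.data$tissue_id %in% exclusions)
  prof1 <- build_profiles(drop_tissues(calls_rep1),
                          min_tissues = params$min_tissues)
  prof2 <- build_profiles(drop_tissues(calls_rep2),
                          min_tissues = params$min_tissues)

  grid <- tidyr::expand_grid(
    pair = ratio_cutoffs,
    dispersion_cutoff = dispersion_cutoffs
  )
  res <- purrr::pmap_dfr(grid, function(pair, dispersion_cutoff) {
    p <- class_params(ratio_lo = pair[1], ratio_hi = pair[2],
                      dispersion_max = dispersion_cutoff,
                      alpha = params$alpha,
                      min_tissues = params$min_tissues,
                      min_significant_tissues = params$min_significant_tissues)
    l1 <- classify_profiles(prof1, p)
    l2 <- classify_profiles(prof2, p)
    joined <- dplyr::inner_join(
      dplyr::select(l1, "site_id", label1 = "class_label"),
      dplyr::select(l2, "site_id", label2 = "class_label"),
      by = "site_id"
    ) |>
      dplyr::filter(.data$label1 != "UNCLASSIFIED",
                    .data$label2 != "UNCLASSIFIED")
    to_binary <- function(x) ifelse(x == "NO_ASE", "NO_ASE", "ASE")
    tibble::tibble(
      ratio_lo = pair[1], ratio_hi = pair[2],
      dispersion_cutoff = dispersion_cutoff,
      excluded_tissues = paste(exclusions, collapse = ";"),
      n_sites = nrow(joined),
      concordance_3class = mean(joined$label1 == joined$label2),
      concordance_2class = mean(to_binary(joined$label1) ==
                                  to_binary(joined$label2))
    )
  })
  class(res) <- c("ase_sweep", class(res))
  res
}
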