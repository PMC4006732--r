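#' Mean-dispersion scatter of classified cross-tissue profiles
#'
#' The classic classification view: each point is a site, x = mean allelic
#' ratio across tissues, y = cross-tissue dispersion (standard deviation),
#' coloured by ASE class.
#'
#' @param object Classified `ase_profiles`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method autoplot ase_profiles
autoplot.ase_profiles <- function(object, ...) {
  df <- tibble::as_tibble(object[c("site_id", "mean_ratio",
                                   "ratio_dispersion", "class_label")])
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_ratio, .data$ratio_dispersion,
                                   colour = .data$class_label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(
      NO_ASE = "firebrick", SHARED_ASE = "steelblue",
      VARIABLE_ASE = "forestgreen", UNCLASSIFIED = "grey60"),
      name = "ASE class") +
    ggplot2::labs(x = "mean allelic ratio (alt / total)",
                  y = "cross-tissue dispersion (sd of ratios)") +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ase_profiles
#' @param profiles Classified `ase_profiles`.
#' @export
plot_ase_classes <- function(profiles) autoplot(profiles)

#' Replicate concordance: mean absolute ratio difference by depth bin
#'
#' @param object An `ase_concordance` tibble from
#'   [replicate_concordance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method autoplot ase_concordance
autoplot.ase_concordance <- function(object, ...) {
  df <- tidyr::unnest(tibble::as_tibble(object[c("tissue_id", "by_depth")]),
                      "by_depth")
  ggplot2::ggplot(df, ggplot2::aes(.data$depth_bin, .data$mean_abs_delta,
                                   group = .data$tissue_id,
                                   colour = .data$tissue_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "read depth bin (min of replicates)",
                  y = "mean |ratio difference| between replicates",
                  colour = "tissue") +
    ggplot2::theme_minimal()
}

#' Classification-reproducibility sweep curves
#'
#' Concordance between replicate classifications as a function of the
#' dispersion cutoff, one line per balanced-band pair and agreement level.
#'
#' @param object An `ase_sweep` tibble from [classification_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method autoplot ase_sweep
autoplot.ase_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(band = sprintf("%.2f-%.2f", .data$ratio_lo,
                                 .data$ratio_hi)) |>
    tidyr::pivot_longer(c("concordance_3class", "concordance_2class"),
                        names_to = "agreement", values_to = "concordance")
  ggplot2::ggplot(df, ggplot2::aes(.data$dispersion_cutoff,
                                   .data$concordance,
                                   colour = .data$band,
                                   linetype = .data$agreement)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "dispersion cutoff",
                  y = "replicate classification concordance",
                  colour = "balanced band", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Allelic ratios by variant class per tissue
#'
#' Boxplots of QC-passing allelic ratios stratified by a site grouping
#' (variant class by default), one panel row of boxes per tissue — the
#' standard view of cohort contrasts such as nonsense-mediated decay.
#'
#' @param calls `ase_calls` tibble.
#' @param sites Site tibble carrying the grouping column.
#' @param grouping Site column to stratify by (default `"variant_class"`).
#' @return A ggplot object.
#' @export
plot_group_ratios <- function(calls, sites, grouping = "variant_class") {
  labels <- sites[[grouping]][match(calls$site_id, sites$site_id)]
  df <- calls |>
    dplyr::mutate(group = labels) |>
    dplyr::filter(.data$qc_pass, !is.na(.data$group))
  ggplot2::ggplot(df, ggplot2::aes(.data$tissue_id, .data$allelic_ratio,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = "allelic ratio (alt / total)",
                  fill = grouping) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
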