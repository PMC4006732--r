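#' Aggregate per-tissue ASE calls into cross-tissue profiles
#'
#' Collects, for each site, the allelic ratios and p-values of its
#' QC-passing calls across tissues (one assay, replicates already merged)
#' and summarises them by the mean ratio and the cross-tissue dispersion.
#' Dispersion is the *population* standard deviation: the tissue panel is
#' the full set under study, not a sample from a larger one, and n is
#' small. Profiles seen in fewer than `min_tissues` tissues are kept but
#' will remain unclassified.
#'
#' @param calls An `ase_calls` tibble from [call_ase()] (single assay,
#'   merged replicates).
#' @param min_tissues Minimum number of QC-passing tissues required for
#'   classification downstream (default 3).
#' @return A tibble of class `ase_profiles`: one row per site with
#'   list-columns `ratios` and `p_values` (named per tissue), `n_tissues`,
#'   `mean_ratio`, `ratio_dispersion`, `n_significant` (p < 0.01 among
#'   QC-passing tissues) and a `class_label` initialised to
#'   `"UNCLASSIFIED"`.
#' @export
build_profiles <- function(calls, min_tissues = 3) {
  require_columns(calls, c("site_id", "tissue_id", "allelic_ratio",
                           "p_value", "qc_pass"), "ASE call table")
  if (length(unique(calls$assay)) > 1) {
    abort("build_profiles expects calls from a single assay")
  }
  dup <- duplicated(calls[c("site_id", "tissue_id")])
  if (any(dup)) {
    abort(sprintf("duplicate tissue entries for site(s): %s (merge replicates first)",
                  paste(unique(calls$site_id[dup]), collapse = ", ")))
  }
  passing <- dplyr::filter(calls, .data$qc_pass, !is.na(.data$allelic_ratio))

  profiles <- passing |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      ratios = list(setNames(.data$allelic_ratio, .data$tissue_id)),
      p_values = list(setNames(.data$p_value, .data$tissue_id)),
      n_tissues = dplyr::n(),
      mean_ratio = mean(.data$allelic_ratio),
      ratio_dispersion = pop_sd(.data$allelic_ratio),
      .groups = "drop"
    ) |>
    dplyr::mutate(class_label = "UNCLASSIFIED")
  class(profiles) <- c("ase_profiles", class(profiles))
  attr(profiles, "min_tissues") <- min_tissues
  profiles
}

# population (divide-by-n) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Classify cross-tissue ASE profiles
#'
#' Partitions profiles into the three cross-tissue ASE patterns using the
#' mean and dispersion of allelic ratios plus per-tissue significance:
#'
#' * `NO_ASE` — mean ratio strictly inside (`ratio_lo`, `ratio_hi`)
#'   (balanced expression) and dispersion strictly below `dispersion_max`;
#' * `SHARED_ASE` — mean ratio strictly outside the balanced band,
#'   dispersion strictly below `dispersion_max`, and at least
#'   `min_significant_tissues` tissues with p below `alpha`;
#' * `VARIABLE_ASE` — dispersion strictly above `dispersion_max` and at
#'   least `min_significant_tissues` significant tissues;
#' * `UNCLASSIFIED` — everything else, including profiles in fewer than
#'   `min_tissues` tissues and exact ties with any cutoff (the cutoffs are
#'   strict inequalities).
#'
#' The classification is deterministic and assigns exactly one label per
#' profile.
#'
#' @param profiles An `ase_profiles` tibble from [build_profiles()].
#' @param params A [class_params()] object.
#' @return `profiles` with `class_label` filled in and an `n_significant`
#'   column (tissues with p < `params$alpha`).
#' @export
classify_profiles <- function(profiles, params = class_params()) {
  params <- as_class_params(params)
  min_tissues <- max(params$min_tissues,
                     attr(profiles, "min_tissues") %||% 1)

  n_sig <- vapply(profiles$p_values,
                  function(p) sum(p < params$alpha), integer(1))
  mean_r <- profiles$mean_ratio
  disp <- profiles$ratio_dispersion

  balanced <- mean_r > params$ratio_lo & mean_r < params$ratio_hi
  imbalanced <- mean_r < params$ratio_lo | mean_r > params$ratio_hi
  low_disp <- disp < params$dispersion_max
  high_disp <- disp > params$dispersion_max
  sig <- n_sig >= params$min_significant_tissues

  label <- rep("UNCLASSIFIED", nrow(profiles))
  label[balanced & low_disp] <- "NO_ASE"
  label[imbalanced & low_disp & sig] <- "SHARED_ASE"
  label[high_disp & sig] <- "VARIABLE_ASE"
  label[profiles$n_tissues < min_tissues] <- "UNCLASSIFIED"

  profiles$n_significant <- n_sig
  profiles$class_label <- label
  attr(profiles, "class_params") <- params
  profiles
}

#' Detect monoallelic expression across tissues
#'
#' A site is monoallelically expressed when, in every testable tissue, its
#' allelic ratio lies in the same extreme tail: all ratios at or above
#' `mono_threshold` (alternate allele expressed) or all at or below
#' `1 - mono_threshold` (reference allele expressed). Sites testable in
#' fewer than `min_testable` tissues are not reported, and a site whose
#' ratios span both tails is never reported.
#'
#' @param profiles An `ase_profiles` tibble.
#' @param mono_threshold Ratio beyond which expression counts as
#'   single-allele (default 0.95; must exceed 0.5).
#' @param min_testable Minimum QC-passing tissues (default 5).
#' @return A tibble with `site_id`, `expressed_allele` (`"ref"`/`"alt"`),
#'   `n_tissues` and `consistent` (same allele favoured in all tissues —
#'   always `TRUE` for reported sites by construction).
#' @export
detect_monoallelic <- function(profiles, mono_threshold = 0.95,
                               min_testable = 5) {
  stopifnot(mono_threshold > 0.5, mono_threshold <= 1)
  res <- purrr::map2_dfr(profiles$site_id, profiles$ratios, function(id, r) {
    if (length(r) < min_testable) return(NULL)
    if (all(r >= mono_threshold)) {
      tibble::tibble(site_id = id, expressed_allele = "alt",
                     n_tissues = length(r), consistent = TRUE)
    } else if (all(r <= 1 - mono_threshold)) {
      tibble::tibble(site_id = id, expressed_allele = "ref",
                     n_tissues = length(r), consistent = TRUE)
    } else {
      NULL
    }
  })
  if (nrow(res) == 0) {
    res <- tibble::tibble(site_id = character(), expressed_allele = character(),
                          n_tissues = integer(), consistent = logical())
  }
  res
}

#' Summarise the range and directional flips of allelic ratios
#'
#' For each site tested in at least `min_tissues` tissues, reports the
#' minimum and maximum allelic ratio over tissues and classifies
#' direction-of-effect flips by fixed thresholds: `major` (< 0.2 in some
#' tissue and > 0.8 in another), `large` (< 0.4 to > 0.8), `moderate`
#' (< 0.2 to > 0.6), else `none`; the most extreme class wins.
#'
#' @param profiles An `ase_profiles` tibble.
#' @param min_tissues Minimum QC-passing tissues (default 3).
#' @return A tibble with `site_id`, `min_ratio`, `max_ratio`, `flip_class`.
#' @export
ratio_range_summary <- function(profiles, min_tissues = 3) {
  keep <- profiles$n_tissues >= min_tissues
  tibble::tibble(
    site_id = profiles$site_id[keep],
    min_ratio = vapply(profiles$ratios[keep], min, numeric(1)),
    max_ratio = vapply(profiles$ratios[keep], max, numeric(1))
  ) |>
    dplyr::mutate(
      flip_class = dplyr::case_when(
        .data$min_ratio < 0.2 & .data$max_ratio > 0.8 ~ "major",
        .data$min_ratio < 0.4 & .data$max_ratio > 0.8 ~ "large",
        .data$min_ratio < 0.2 & .data$max_ratio > 0.6 ~ "moderate",
        TRUE ~ "none"
      )
    )
}
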