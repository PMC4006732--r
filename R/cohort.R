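#' Remove nonsense sites with reference-skewed DNA allelic balance
#'
#' Apparent depletion of a nonsense allele in RNA can be mimicked by
#' genotyping error or poor mappability of the non-reference allele. Those
#' artefacts also skew the *DNA* allelic ratio, so a nonsense site is
#' removed when its exome-DNA alternate-allele ratio falls below
#' `min_dna_alt_ratio` in **every** DNA sample with a QC-passing call.
#' Non-nonsense sites pass through untouched; a nonsense site with no DNA
#' call in any sample is retained with a warning.
#'
#' @param sites Site tibble.
#' @param dna_calls `ase_calls` for the `exome_dna` assay (tissues are the
#'   DNA samples).
#' @param min_dna_alt_ratio Threshold on the DNA alternate-allele ratio
#'   (default 0.2).
#' @return The retained subset of `sites`.
#' @export
dna_bias_filter <- function(sites, dna_calls, min_dna_alt_ratio = 0.2) {
  sites <- validate_sites(sites)
  require_columns(dna_calls, c("site_id", "allelic_ratio", "qc_pass"),
                  "DNA call table")
  if (!all(dna_calls$assay == "exome_dna")) {
    abort("dna_bias_filter expects exome_dna-assay calls")
  }
  nonsense <- sites$site_id[sites$variant_class == "nonsense"]
  ok <- dplyr::filter(dna_calls, .data$qc_pass,
                      .data$site_id %in% nonsense)
  verdict <- ok |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(drop = all(.data$allelic_ratio < min_dna_alt_ratio),
                     .groups = "drop")
  uncovered <- setdiff(nonsense, verdict$site_id)
  if (length(uncovered) > 0) {
    warn(sprintf("%d nonsense site(s) have no QC-passing DNA call and are retained: %s",
                 length(uncovered), paste(head(uncovered, 5), collapse = ", ")))
  }
  dropped <- verdict$site_id[verdict$drop]
  dplyr::filter(sites, !.data$site_id %in% dropped)
}

#' Stratify sites into rare and common by allele frequency
#'
#' Common sites have a minor allele frequency strictly above `maf_cutoff`;
#' everything else — low frequency, private (absent from reference
#' panels), or missing frequency — is rare. Sites with neither a frequency
#' nor a privacy flag are assigned rare with a warning. Every site lands
#' in exactly one stratum.
#'
#' @param sites Site tibble with `maf` and `is_private` columns.
#' @param maf_cutoff Frequency cutoff (default 0.05).
#' @return `sites` with an added `frequency_stratum` column
#'   (`"rare"`/`"common"`).
#' @export
stratify_by_frequency <- function(sites, maf_cutoff = 0.05) {
  sites <- validate_sites(sites)
  require_columns(sites, c("maf", "is_private"), "site table")
  unknown <- is.na(sites$maf) & !sites$is_private
  if (any(unknown)) {
    warn(sprintf("%d site(s) with no allele frequency and not flagged private; assigned rare",
                 sum(unknown)))
  }
  dplyr::mutate(
    sites,
    frequency_stratum = dplyr::if_else(
      !is.na(.data$maf) & .data$maf > maf_cutoff & !.data$is_private,
      "common", "rare")
  )
}

#' Compare allelic ratios between site groups per tissue
#'
#' Two-sample t-test (Welch by default) on the QC-passing allelic ratios of
#' two site groups, run separately per tissue. Grouping can be by variant
#' class (`grouping = "variant_class"`) or frequency stratum
#' (`"frequency_stratum"`, see [stratify_by_frequency()]). Groups with
#' fewer than 2 calls in a tissue are reported with missing statistics
#' rather than dropped.
#'
#' @param calls `ase_calls` tibble (merged replicates).
#' @param sites Site tibble carrying the grouping column.
#' @param group_a,group_b Labels of the two groups to compare.
#' @param grouping Name of the site column holding the labels
#'   (default `"variant_class"`).
#' @param per_tissue Compare within each tissue (default) or pooled over
#'   tissues.
#' @param var_equal Use the pooled-variance (classic Student) test instead
#'   of Welch (default FALSE).
#' @return A tibble with one row per tissue: group sizes, mean ratios,
#'   `t_statistic`, `p_value`.
#' @export
compare_groups <- function(calls, sites, group_a, group_b,
                           grouping = "variant_class", per_tissue = TRUE,
                           var_equal = FALSE) {
  sites <- validate_sites(sites)
  if (!grouping %in% names(sites)) {
    abort(sprintf("unknown grouping column '%s' in site table", grouping))
  }
  labels <- sites[[grouping]][match(calls$site_id, sites$site_id)]
  df <- calls |>
    dplyr::mutate(group = labels) |>
    dplyr::filter(.data$qc_pass, !is.na(.data$allelic_ratio),
                  .data$group %in% c(group_a, group_b))
  if (!per_tissue) df$tissue_id <- "all"

  df |>
    dplyr::group_by(.data$tissue_id) |>
    dplyr::group_modify(function(d, key) {
      a <- d$allelic_ratio[d$group == group_a]
      b <- d$allelic_ratio[d$group == group_b]
      res <- tibble::tibble(
        group_a = group_a, group_b = group_b,
        n_a = length(a), n_b = length(b),
        mean_ratio_a = if (length(a)) mean(a) else NA_real_,
        mean_ratio_b = if (length(b)) mean(b) else NA_real_,
        t_statistic = NA_real_, p_value = NA_real_
      )
      if (length(a) >= 2 && length(b) >= 2 &&
          (sd(a) > 0 || sd(b) > 0)) {
        tt <- t.test(a, b, var.equal = var_equal)
        res$t_statistic <- unname(tt$statistic)
        res$p_value <- tt$p.value
      } else if (length(a) >= 2 && length(b) >= 2) {
        # identical constant vectors: no evidence of difference
        res$t_statistic <- 0
        res$p_value <- 1
      }
      res
    }) |>
    dplyr::ungroup()
}

#' Enrichment of a site flag in one ASE class versus another
#'
#' Builds the 2x2 table of flagged/unflagged sites in two ASE classes
#' (e.g. deleteriousness in shared-ASE vs no-ASE sites) and tests
#' association with a two-sided Fisher exact test, computed by direct
#' hypergeometric enumeration: the p-value sums the probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's. The odds ratio is taken from the raw counts
#' (`ad / bc`); 0.5 is added to every cell only when a zero cell makes the
#' ratio undefined, and the result is then flagged as corrected.
#'
#' @param profiles Classified `ase_profiles` (see [classify_profiles()]).
#' @param sites Site tibble.
#' @param class_a,class_b ASE class labels to contrast (e.g.
#'   `"SHARED_ASE"`, `"NO_ASE"`).
#' @param flag Either the name of a logical site column, or a function of
#'   the site tibble returning a logical vector. The default flags
#'   deleterious sites: `variant_class != "control"`.
#' @return An object of class `ase_enrichment`: the 2x2 `table`,
#'   `odds_ratio`, `p_value`, `haldane_corrected`, and the class/flag
#'   labels. `tidy()`/`glance()` methods are provided.
#' @export
fisher_enrichment <- function(profiles, sites, class_a = "SHARED_ASE",
                              class_b = "NO_ASE",
                              flag = function(s) s$variant_class != "control") {
  sites <- validate_sites(sites)
  flag_val <- if (is.function(flag)) flag(sites) else sites[[flag]]
  if (is.null(flag_val) || !is.logical(flag_val)) {
    abort("flag must be a logical site column name or a function returning one")
  }
  flagged_ids <- sites$site_id[flag_val]

  in_class <- function(cl) profiles$site_id[profiles$class_label == cl]
  ids_a <- in_class(class_a)
  ids_b <- in_class(class_b)
  if (length(ids_a) == 0 || length(ids_b) == 0) {
    abort(sprintf("empty ASE class: %s",
                  paste(c(class_a, class_b)[c(length(ids_a), length(ids_b)) == 0],
                        collapse = ", ")))
  }
  tab <- matrix(c(sum(ids_a %in% flagged_ids), sum(!ids_a %in% flagged_ids),
                  sum(ids_b %in% flagged_ids), sum(!ids_b %in% flagged_ids)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c(class_a, class_b),
                                c("flagged", "unflagged")))
  fisher_from_table(tab, class_a = class_a, class_b = class_b)
}

#' Fisher exact test from an explicit 2x2 table
#'
#' @param tab A 2x2 matrix of non-negative integer counts: rows = classes,
#'   columns = flagged/unflagged.
#' @param class_a,class_b Optional row labels carried into the result.
#' @return An `ase_enrichment` object (see [fisher_enrichment()]).
#' @export
fisher_from_table <- function(tab, class_a = "A", class_b = "B") {
  stopifnot(is.matrix(tab), all(dim(tab) == 2))
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("table cells must be non-negative integers")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]

  # condition on the margins: x = top-left cell ranges over all feasible
  # values; p-value sums dhyper mass over tables no more probable than ours
  m <- a + b            # row 1 total
  k <- a + c_           # column 1 total
  n2 <- c_ + d          # row 2 total
  lo <- max(0, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, m, n2, k)
  p_obs <- probs[support == a]
  p_value <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))

  haldane <- b * c_ == 0    # undefined denominator is the only correction case
  or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
        else (a * d) / (b * c_)

  structure(
    list(table = tab, odds_ratio = or, p_value = p_value,
         haldane_corrected = haldane, class_a = class_a, class_b = class_b),
    class = "ase_enrichment"
  )
}

#' @exportS3Method print ase_enrichment
print.ase_enrichment <- function(x, ...) {
  cat(sprintf("Fisher enrichment: %s vs %s\n", x$class_a, x$class_b))
  print(x$table)
  cat(sprintf("odds ratio = %.3f%s, two-sided p = %.4g\n",
              x$odds_ratio,
              if (x$haldane_corrected) " (Haldane-corrected)" else "",
              x$p_value))
  invisible(x)
}

#' @exportS3Method tidy ase_enrichment
tidy.ase_enrichment <- function(x, ...) {
  tibble::tibble(
    class_a = x$class_a, class_b = x$class_b,
    flagged_a = x$table[1, 1], unflagged_a = x$table[1, 2],
    flagged_b = x$table[2, 1], unflagged_b = x$table[2, 2],
    odds_ratio = x$odds_ratio, p_value = x$p_value,
    haldane_corrected = x$haldane_corrected
  )
}

#' @exportS3Method glance ase_enrichment
glance.ase_enrichment <- function(x, ...) {
  tibble::tibble(
    odds_ratio = x$odds_ratio, p_value = x$p_value,
    n = sum(x$table),
    prop_flagged_a = x$table[1, 1] / sum(x$table[1, ]),
    prop_flagged_b = x$table[2, 1] / sum(x$table[2, ])
  )
}
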