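#' Configuration for the multi-tissue allele-count simulator
#'
#' Returns the generator parameters with defaults chosen to emulate the
#' structure of a single-individual, ten-tissue ASE study measured by
#' RNA-seq, targeted deep mmPCR-seq and exome DNA sequencing:
#'
#' * ASE classes — balanced (no ASE), shared ASE (one direction in all
#'   tissues, alternate-allele mean 0.2), variable ASE (tissue-level means
#'   scattered around 0.5 with sd 0.3) and monoallelic (0.99/0.01), in
#'   proportions 0.72/0.20/0.05/0.03;
#' * variant classes — control, deleterious nsSNP and nonsense in
#'   proportions 205:74:50. Nonsense sites are subject to
#'   nonsense-mediated decay in RNA-derived assays: their alternate-allele
#'   mean is overridden to `nmd_alt_mean_rare` (0.15) or
#'   `nmd_alt_mean_common` (0.30) by rarity, while DNA stays at 0.5;
#' * reference-mapping bias — an odds multiplier `ref_bias_factor` >= 1 on
#'   the reference allele at read sampling, so the observed
#'   alternate-read probability is `mu / (beta * (1 - mu) + mu)`;
#' * replicate noise — beta-binomial counts with intra-class correlation
#'   `overdispersion_rho` (inflatable for designated high-noise tissues,
#'   emulating low post-mortem RNA quality);
#' * depth — mmPCR negative-binomial around mean 2000 independent of
#'   expression; RNA-seq depth tied to a per-gene log-normal expression
#'   level with per-tissue variation, then Poisson; exome DNA around 80.
#'
#' @param n_sites Number of heterozygous sites (default 500).
#' @param tissue_ids Tissue panel (default a ten-somatic-tissue panel).
#' @param replicates_per_tissue Technical replicates (default 2).
#' @param class_proportions Named proportions over no_ase/shared_ase/
#'   variable_ase/monoallelic; must sum to 1.
#' @param variant_class_proportions Named proportions over control/
#'   deleterious_nsSNP/nonsense; must sum to 1.
#' @param rare_fraction_nonsense Fraction of nonsense sites that are rare
#'   (private) (default 0.5).
#' @param nmd_alt_mean_rare,nmd_alt_mean_common RNA alternate-allele means
#'   for rare/common nonsense sites (defaults 0.15/0.30).
#' @param shared_ase_alt_mean Alternate-allele mean for shared-ASE sites
#'   (default 0.20; direction randomised per site).
#' @param within_class_tissue_sd Tissue-to-tissue sd of the true mean
#'   within shared/nonsense classes (default 0.03).
#' @param variable_ase_tissue_sd Tissue-level sd for variable-ASE sites
#'   (default 0.30).
#' @param ref_bias_factor Reference-allele odds multiplier beta >= 1
#'   (default 1.05).
#' @param overdispersion_rho Beta-binomial intra-class correlation in
#'   \[0, 1) (default 0.005).
#' @param high_noise_tissues Tissues with inflated overdispersion.
#' @param high_noise_rho Their intra-class correlation (default 0.05).
#' @param mmpcr_depth_mean,mmpcr_depth_size Negative-binomial mmPCR depth
#'   (defaults 2000, size 10).
#' @param rna_depth_meanlog,rna_depth_sdlog Log-normal per-gene expression
#'   feeding Poisson RNA depth (defaults log(60), 1).
#' @param rna_tissue_sdlog Per-tissue log-normal spread of RNA depth
#'   (default 0.5).
#' @param dna_depth_mean,dna_depth_size Negative-binomial exome depth
#'   (defaults 80, size 10).
#' @param other_error_rate Per-read probability of a third/fourth base
#'   (default 0.002).
#' @param intergenic_fraction Fraction of sites outside genes
#'   (default 0.02).
#' @param seed Integer seed making the dataset reproducible (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 500,
                       tissue_ids = c("cerebellum", "frontal_lobe",
                                      "pancreas", "stomach",
                                      "small_intestine", "colon", "heart",
                                      "lung", "liver", "skeletal_muscle"),
                       replicates_per_tissue = 2,
                       class_proportions = c(no_ase = 0.72,
                                             shared_ase = 0.20,
                                             variable_ase = 0.05,
                                             monoallelic = 0.03),
                       variant_class_proportions =
                         c(control = 205, deleterious_nsSNP = 74,
                           nonsense = 50) / 329,
                       rare_fraction_nonsense = 0.5,
                       nmd_alt_mean_rare = 0.15,
                       nmd_alt_mean_common = 0.30,
                       shared_ase_alt_mean = 0.20,
                       within_class_tissue_sd = 0.03,
                       variable_ase_tissue_sd = 0.30,
                       ref_bias_factor = 1.05,
                       overdispersion_rho = 0.005,
                       high_noise_tissues = character(0),
                       high_noise_rho = 0.05,
                       mmpcr_depth_mean = 2000,
                       mmpcr_depth_size = 10,
                       rna_depth_meanlog = log(60),
                       rna_depth_sdlog = 1,
                       rna_tissue_sdlog = 0.5,
                       dna_depth_mean = 80,
                       dna_depth_size = 10,
                       other_error_rate = 0.002,
                       intergenic_fraction = 0.02,
                       seed = 1L) {
  cfg <- as.list(environment())
  check_props <- function(p, names_needed, what) {
    if (!setequal(names(p), names_needed) || abs(sum(p) - 1) > 1e-8 ||
        any(p < 0)) {
      abort(sprintf("%s must be named proportions over {%s} summing to 1",
                    what, paste(names_needed, collapse = ", ")))
    }
  }
  check_props(class_proportions,
              c("no_ase", "shared_ase", "variable_ase", "monoallelic"),
              "class_proportions")
  check_props(variant_class_proportions, VARIANT_CLASS_LEVELS,
              "variant_class_proportions")
  stopifnot(
    n_sites >= 1, length(tissue_ids) >= 1, replicates_per_tissue >= 1,
    ref_bias_factor >= 1,
    overdispersion_rho >= 0, overdispersion_rho < 1,
    nmd_alt_mean_rare > 0, nmd_alt_mean_rare < 1,
    nmd_alt_mean_common > 0, nmd_alt_mean_common < 1,
    shared_ase_alt_mean > 0, shared_ase_alt_mean < 1,
    rare_fraction_nonsense >= 0, rare_fraction_nonsense <= 1,
    all(high_noise_tissues %in% tissue_ids)
  )
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-tissue, multi-replicate allele-count dataset
#'
#' Draws sites, per-tissue true alternate-allele fractions by ASE class,
#' applies the reference-mapping bias at read sampling, and generates
#' beta-binomial read counts per replicate for three assays (mmPCR,
#' RNA-seq, exome DNA). Ground truth is returned alongside so recovery of
#' bias, classes and cohort contrasts can be tested. Identical
#' configuration (including its `seed`) yields an identical dataset.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_dataset` with `sites` (site tibble),
#'   `counts` (one tibble of count records for all assays), and `truth`
#'   (per-site tibble: drawn and effective class, variant class,
#'   frequency stratum, list-columns of per-tissue true RNA means `mu`
#'   and post-bias alternate-read probabilities `theta`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_sites
  tissues <- config$tissue_ids
  nt <- length(tissues)
  beta <- config$ref_bias_factor

  ids <- sprintf("S%04d", seq_len(n))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  class_drawn <- sample(names(config$class_proportions), n, replace = TRUE,
                        prob = config$class_proportions)
  variant_class <- sample(VARIANT_CLASS_LEVELS, n, replace = TRUE,
                          prob = config$variant_class_proportions)
  is_nonsense <- variant_class == "nonsense"
  nonsense_rare <- is_nonsense &
    runif(n) < config$rare_fraction_nonsense

  # allele frequencies: controls and common nonsense are common panel
  # variants; deleterious nsSNPs and rare nonsense are private
  maf <- rep(NA_real_, n)
  is_private <- rep(FALSE, n)
  common_like <- variant_class == "control" | (is_nonsense & !nonsense_rare)
  maf[common_like] <- runif(sum(common_like), 0.051, 0.5)
  is_private[variant_class == "deleterious_nsSNP" | nonsense_rare] <- TRUE

  is_intragenic <- runif(n) >= config$intergenic_fraction

  sites <- tibble::tibble(
    site_id = ids,
    chrom = paste0("chr", (seq_len(n) - 1) %% 22 + 1),
    pos = 1000L + 10L * seq_len(n),
    ref_base = ref, alt_base = alt,
    gene_id = sprintf("GENE%04d", seq_len(n)),
    variant_class = variant_class,
    maf = maf, is_private = is_private,
    is_intragenic = is_intragenic
  )

  clamp <- function(x) pmin(pmax(x, 0.02), 0.98)
  draw_mu <- function(cls) {
    switch(cls,
      no_ase = rep(0.5, nt),
      shared_ase = {
        m <- if (runif(1) < 0.5) config$shared_ase_alt_mean
             else 1 - config$shared_ase_alt_mean
        clamp(rnorm(nt, m, config$within_class_tissue_sd))
      },
      variable_ase = clamp(rnorm(nt, 0.5, config$variable_ase_tissue_sd)),
      monoallelic = rep(if (runif(1) < 0.5) 0.99 else 0.01, nt)
    )
  }
  mu_rna <- lapply(class_drawn, draw_mu)

  # nonsense-mediated decay overrides the RNA-side class: the nonsense
  # allele is consistently depleted, more strongly when rare
  true_class <- class_drawn
  for (i in which(is_nonsense)) {
    m <- if (nonsense_rare[i]) config$nmd_alt_mean_rare
         else config$nmd_alt_mean_common
    mu_rna[[i]] <- clamp(rnorm(nt, m, config$within_class_tissue_sd))
    true_class[i] <- "shared_ase"
  }
  mu_dna <- rep(list(rep(0.5, nt)), n)

  # bias at read sampling: reference reads map with odds multiplied by beta
  apply_bias <- function(mu) mu / (beta * (1 - mu) + mu)
  theta_rna <- lapply(mu_rna, apply_bias)
  theta_dna <- lapply(mu_dna, apply_bias)

  rho_by_tissue <- setNames(rep(config$overdispersion_rho, nt), tissues)
  rho_by_tissue[config$high_noise_tissues] <- config$high_noise_rho

  expr_level <- rlnorm(n, config$rna_depth_meanlog, config$rna_depth_sdlog)

  sim_assay <- function(assay, theta, reps, depth_fun, rho_vec) {
    grid <- tidyr::expand_grid(site = seq_len(n), tissue = seq_len(nt),
                               rep = seq_len(reps))
    depth <- depth_fun(grid)
    th <- vapply(seq_len(nrow(grid)), function(k)
      theta[[grid$site[k]]][grid$tissue[k]], numeric(1))
    rho <- rho_vec[grid$tissue]
    p <- ifelse(rho > 0,
                rbeta(nrow(grid), th * (1 / pmax(rho, 1e-12) - 1),
                      (1 - th) * (1 / pmax(rho, 1e-12) - 1)),
                th)
    alt_n <- rbinom(nrow(grid), depth, p)
    other_n <- rbinom(nrow(grid), depth, config$other_error_rate)
    tibble::tibble(
      site_id = ids[grid$site],
      tissue_id = tissues[grid$tissue],
      replicate_id = paste0("r", grid$rep),
      assay = assay,
      ref_count = as.integer(depth - alt_n),
      alt_count = as.integer(alt_n),
      other_count = as.integer(other_n)
    )
  }

  counts <- dplyr::bind_rows(
    sim_assay("mmpcr", theta_rna, config$replicates_per_tissue,
              function(g) rnbinom(nrow(g), mu = config$mmpcr_depth_mean,
                                  size = config$mmpcr_depth_size),
              rho_by_tissue),
    sim_assay("rna_seq", theta_rna, 1,
              function(g) rpois(nrow(g), expr_level[g$site] *
                                  rlnorm(nrow(g), 0,
                                         config$rna_tissue_sdlog)),
              rho_by_tissue),
    sim_assay("exome_dna", theta_dna, 1,
              function(g) rnbinom(nrow(g), mu = config$dna_depth_mean,
                                  size = config$dna_depth_size),
              setNames(rep(0, nt), tissues))
  )
  # DNA comes from two samples, not the full tissue panel
  counts <- dplyr::filter(
    counts,
    .data$assay != "exome_dna" |
      .data$tissue_id %in% tissues[seq_len(min(2, nt))]
  )

  truth <- tibble::tibble(
    site_id = ids,
    class_drawn = class_drawn,
    true_class = true_class,
    variant_class = variant_class,
    frequency_stratum = ifelse(is_private | (!is.na(maf) & maf <= 0.05) |
                                 is.na(maf), "rare", "common"),
    mu = lapply(mu_rna, setNames, tissues),
    theta = lapply(theta_rna, setNames, tissues)
  )

  structure(list(sites = sites, counts = counts, truth = truth,
                 config = config),
            class = "sim_dataset")
}

#' Compare recovered ASE class labels with simulation truth
#'
#' Maps classified profiles back onto simulation truth: a site's predicted
#' label is `monoallelic` when [detect_monoallelic()] reports it (the
#' classifier itself has no monoallelic label — those sites satisfy the
#' shared-ASE geometry), otherwise the lower-cased classifier label.
#'
#' @param profiles Classified `ase_profiles`.
#' @param truth Truth tibble from [simulate_dataset()].
#' @param mono_threshold,min_testable Passed to [detect_monoallelic()];
#'   `min_testable` defaults to the classifier's minimum tissue count so
#'   monoallelic detection covers the same site universe.
#' @return A tibble with `site_id`, `true_class`, `predicted_class`,
#'   `correct`; sites without a classified profile are predicted
#'   `unclassified`.
#' @export
class_recovery <- function(profiles, truth, mono_threshold = 0.95,
                           min_testable = 3) {
  mono <- detect_monoallelic(profiles, mono_threshold, min_testable)
  pred <- tolower(profiles$class_label)
  pred[profiles$site_id %in% mono$site_id] <- "monoallelic"
  res <- truth |>
    dplyr::select("site_id", "true_class") |>
    dplyr::left_join(tibble::tibble(site_id = profiles$site_id,
                                    predicted_class = pred),
                     by = "site_id") |>
    dplyr::mutate(
      predicted_class = dplyr::coalesce(.data$predicted_class,
                                        "unclassified"),
      correct = .data$predicted_class == .data$true_class
    )
  res
}

#' Write a simulated dataset to disk as plain-text fixtures
#'
#' Emits everything the pipeline readers consume: a minimal VCF (v4.2)
#' with two heterozygous DNA-sample genotype columns, a site annotation
#' TSV, one count TSV per assay, and a truth TSV with per-tissue true
#' means flattened into columns. Regeneration with the same configuration
#' is byte-identical.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly; the simulated
#'   dataset as attribute `"dataset"`.
#' @export
end_to_end_fixture <- function(config = sim_config(), dir = tempdir()) {
  ds <- simulate_dataset(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "sites.vcf"),
    annotation = file.path(dir, "sites_annotation.tsv"),
    sites = file.path(dir, "sites.tsv"),
    counts_mmpcr = file.path(dir, "counts_mmpcr.tsv"),
    counts_rna = file.path(dir, "counts_rna_seq.tsv"),
    counts_dna = file.path(dir, "counts_exome_dna.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_sites_vcf(ds$sites, paths["vcf"])
  readr::write_tsv(
    dplyr::select(ds$sites, "chrom", "pos", "ref_base", "alt_base",
                  "gene_id", "variant_class", "maf", "is_private",
                  "is_intragenic"),
    paths["annotation"])
  write_site_table(ds$sites, paths["sites"])
  write_count_table(dplyr::filter(ds$counts, .data$assay == "mmpcr"),
                    paths["counts_mmpcr"])
  write_count_table(dplyr::filter(ds$counts, .data$assay == "rna_seq"),
                    paths["counts_rna"])
  write_count_table(dplyr::filter(ds$counts, .data$assay == "exome_dna"),
                    paths["counts_dna"])
  truth_flat <- ds$truth |>
    dplyr::mutate(mu = purrr::map_chr(.data$mu, ~ paste(signif(.x, 6),
                                                        collapse = ";")),
                  theta = purrr::map_chr(.data$theta,
                                         ~ paste(signif(.x, 6),
                                                 collapse = ";")))
  readr::write_tsv(truth_flat, paths["truth"])
  out <- structure(paths, dataset = ds)
  invisible(out)
}

# minimal VCF 4.2 with two het DNA samples, consistent with read_het_sites
write_sites_vcf <- function(sites, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "dna_frontal_lobe", "dna_small_intestine", sep = "\t")
  )
  body <- paste(sites$chrom, sites$pos, sites$site_id, sites$ref_base,
                sites$alt_base, ".", "PASS", ".", "GT", "0/1", "0/1",
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
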