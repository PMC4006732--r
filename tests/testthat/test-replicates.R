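two_rep_counts <- function(ref1, alt1, ref2, alt2, tissue = "liver",
                           ids = NULL) {
  dplyr::bind_rows(
    make_counts(ref1, alt1, site_id = ids, tissue_id = tissue,
                replicate_id = "r1"),
    make_counts(ref2, alt2, site_id = ids, tissue_id = tissue,
                replicate_id = "r2")
  )
}

test_that("replicate merging sums counts and conserves reads", {
  counts <- two_rep_counts(10, 20, 30, 40)
  merged <- merge_replicates(counts)
  expect_equal(merged$ref_count, 40L)
  expect_equal(merged$alt_count, 60L)
  expect_equal(merged$replicate_id, "merged")
  expect_equal(sum(merged$ref_count + merged$alt_count + merged$other_count),
               sum(counts$ref_count + counts$alt_count + counts$other_count))

  # single replicate passes through unchanged
  single <- make_counts(7, 9)
  m <- merge_replicates(single)
  expect_equal(m$ref_count, 7L)
  expect_equal(m$alt_count, 9L)

  # the merged test equals the summed-count test by definition
  expect_identical(binomial_ase_test(merged$ref_count, merged$alt_count, 0.5),
                   binomial_ase_test(40, 60, 0.5))
})

test_that("identical replicates give r = 1 and zero deltas", {
  set.seed(3)
  n <- 30
  ref <- rbinom(n, 500, runif(n, 0.2, 0.8))
  counts1 <- make_counts(ref, 500 - ref, site_id = sprintf("S%03d", 1:n))
  sites <- make_sites(n)
  calls <- call_ase(counts1, sites, flat_bias(0.5))
  rep <- replicate_concordance(calls, calls)
  expect_equal(rep$pearson_r, 1)
  deltas <- rep$by_depth[[1]]$mean_abs_delta
  expect_true(all(deltas[!is.nan(deltas)] == 0))
})

test_that("fewer than three shared sites leaves r missing with warning", {
  counts <- make_counts(c(100, 120), c(100, 80),
                        site_id = c("S001", "S002"))
  calls <- call_ase(counts, make_sites(2), flat_bias(0.5))
  expect_warning(rep <- replicate_concordance(calls, calls), "fewer than 3")
  expect_true(is.na(rep$pearson_r))
})

test_that("simulated replicates at depth 2000 with rho 0.005 are tightly concordant", {
  cfg <- sim_config(n_sites = 150, seed = 301,
                    tissue_ids = c("liver", "heart"))
  ds <- simulate_dataset(cfg)
  mm <- dplyr::filter(ds$counts, assay == "mmpcr")
  bias <- estimate_reference_bias(mm)
  c1 <- call_ase(dplyr::filter(mm, replicate_id == "r1"), ds$sites, bias)
  c2 <- call_ase(dplyr::filter(mm, replicate_id == "r2"), ds$sites, bias)
  rep <- replicate_concordance(c1, c2)
  expect_true(all(rep$pearson_r > 0.93))
})

test_that("mean absolute replicate delta decreases with depth", {
  set.seed(407)
  # binomial-only noise: delta scales as 1/sqrt(depth)
  depths <- c(30, 150, 400, 1200, 5000)
  n_per <- 60
  recs <- dplyr::bind_rows(lapply(seq_along(depths), function(d) {
    ids <- sprintf("S%d_%02d", d, 1:n_per)
    r1 <- rbinom(n_per, depths[d], 0.5)
    r2 <- rbinom(n_per, depths[d], 0.5)
    dplyr::bind_rows(
      make_counts(r1, depths[d] - r1, site_id = ids, replicate_id = "r1"),
      make_counts(r2, depths[d] - r2, site_id = ids, replicate_id = "r2")
    )
  }))
  sites <- make_sites(1)
  sites <- tibble::tibble(site_id = unique(recs$site_id), chrom = "chr1",
                          pos = seq_along(unique(recs$site_id)) * 10L,
                          ref_base = "C", alt_base = "T",
                          gene_id = NA_character_,
                          variant_class = "control", maf = 0.2,
                          is_private = FALSE, is_intragenic = TRUE)
  bias <- flat_bias(0.5)
  c1 <- call_ase(dplyr::filter(recs, replicate_id == "r1"), sites, bias)
  c2 <- call_ase(dplyr::filter(recs, replicate_id == "r2"), sites, bias)
  rep <- replicate_concordance(c1, c2)
  bd <- rep$by_depth[[1]]
  observed <- bd$mean_abs_delta[bd$n > 0]
  expect_true(all(diff(observed) < 0))
})

test_that("classification sweep is perfect on identical replicates", {
  cfg <- sim_config(n_sites = 60, seed = 99,
                    tissue_ids = paste0("t", 1:4))
  ds <- simulate_dataset(cfg)
  mm <- dplyr::filter(ds$counts, assay == "mmpcr", replicate_id == "r1")
  bias <- estimate_reference_bias(mm)
  calls <- call_ase(mm, ds$sites, bias)
  sweep <- classification_sweep(calls, calls,
                                dispersion_cutoffs = c(0.1, 0.2))
  expect_equal(nrow(sweep), 4)  # 2 bands x 2 cutoffs
  expect_true(all(sweep$concordance_3class == 1))
  expect_true(all(sweep$concordance_2class == 1))
})

test_that("binary concordance never falls below 3-class concordance", {
  cfg <- sim_config(n_sites = 120, seed = 555,
                    tissue_ids = paste0("t", 1:5),
                    overdispersion_rho = 0.02)
  ds <- simulate_dataset(cfg)
  mm <- dplyr::filter(ds$counts, assay == "mmpcr")
  bias <- estimate_reference_bias(mm)
  c1 <- call_ase(dplyr::filter(mm, replicate_id == "r1"), ds$sites, bias)
  c2 <- call_ase(dplyr::filter(mm, replicate_id == "r2"), ds$sites, bias)
  sweep <- classification_sweep(c1, c2)
  expect_true(all(sweep$concordance_2class >= sweep$concordance_3class))
  expect_error(classification_sweep(c1, c2, ratio_cutoffs = list()),
               "empty")
})

test_that("excluding a high-noise tissue raises sweep concordance", {
  cfg <- sim_config(n_sites = 150, seed = 777,
                    tissue_ids = paste0("t", 1:5),
                    high_noise_tissues = "t5", high_noise_rho = 0.2)
  ds <- simulate_dataset(cfg)
  mm <- dplyr::filter(ds$counts, assay == "mmpcr")
  bias <- estimate_reference_bias(mm)
  c1 <- call_ase(dplyr::filter(mm, replicate_id == "r1"), ds$sites, bias)
  c2 <- call_ase(dplyr::filter(mm, replicate_id == "r2"), ds$sites, bias)
  with_noise <- classification_sweep(c1, c2,
                                     ratio_cutoffs = list(c(0.35, 0.65)),
                                     dispersion_cutoffs = 0.2)
  without <- classification_sweep(c1, c2,
                                  ratio_cutoffs = list(c(0.35, 0.65)),
                                  dispersion_cutoffs = 0.2,
                                  exclusions = "t5")
  expect_gte(without$concordance_3class, with_noise$concordance_3class)
})
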