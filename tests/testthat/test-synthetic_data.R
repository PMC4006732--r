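test_that("simulation is deterministic in the seed and schema-stable", {
  cfg <- sim_config(n_sites = 40, seed = 5, tissue_ids = paste0("t", 1:3))
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$sites, d2$sites)

  d3 <- simulate_dataset(sim_config(n_sites = 40, seed = 6,
                                    tissue_ids = paste0("t", 1:3)))
  expect_false(identical(d1$counts$alt_count, d3$counts$alt_count))
  expect_identical(names(d1$counts), names(d3$counts))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(class_proportions = c(no_ase = 0.5,
                                                shared_ase = 0.5,
                                                variable_ase = 0.2,
                                                monoallelic = 0)),
               "summing to 1")
  expect_error(sim_config(ref_bias_factor = 0.9))
  expect_error(sim_config(overdispersion_rho = 1))
  expect_error(sim_config(high_noise_tissues = "not_a_tissue"))
})

test_that("balanced sites at extreme depth have ratio 0.5 without bias", {
  cfg <- sim_config(n_sites = 1, seed = 11, tissue_ids = "t1",
                    class_proportions = c(no_ase = 1, shared_ase = 0,
                                          variable_ase = 0, monoallelic = 0),
                    variant_class_proportions = c(control = 1,
                                                  deleterious_nsSNP = 0,
                                                  nonsense = 0),
                    ref_bias_factor = 1, overdispersion_rho = 0,
                    mmpcr_depth_mean = 1e6, mmpcr_depth_size = 1e6)
  ds <- simulate_dataset(cfg)
  mm <- dplyr::filter(ds$counts, assay == "mmpcr")
  ratio <- mm$alt_count / (mm$ref_count + mm$alt_count)
  expect_true(all(abs(ratio - 0.5) < 0.002))
})

test_that("the mapping-bias odds model gives ref fraction beta/(beta+1) at mu = 0.5", {
  beta <- 1.2
  cfg <- sim_config(n_sites = 200, seed = 21, tissue_ids = "t1",
                    class_proportions = c(no_ase = 1, shared_ase = 0,
                                          variable_ase = 0, monoallelic = 0),
                    variant_class_proportions = c(control = 1,
                                                  deleterious_nsSNP = 0,
                                                  nonsense = 0),
                    ref_bias_factor = beta, overdispersion_rho = 0)
  ds <- simulate_dataset(cfg)
  expect_true(all(abs(purrr::map_dbl(ds$truth$theta, 1) -
                        (1 - beta / (beta + 1))) < 1e-12))
  mm <- dplyr::filter(ds$counts, assay == "mmpcr")
  ref_frac <- sum(mm$ref_count) / sum(mm$ref_count + mm$alt_count)
  expect_lt(abs(ref_frac - beta / (beta + 1)), 0.01)
})

test_that("class and variant-class frequencies track configured proportions", {
  cfg <- sim_config(n_sites = 1000, seed = 7)
  ds <- simulate_dataset(cfg)
  drawn <- table(ds$truth$class_drawn) / 1000
  for (cl in names(cfg$class_proportions)) {
    expect_lt(abs(drawn[[cl]] - cfg$class_proportions[[cl]]), 0.03,
              label = cl)
  }
  vc <- table(ds$truth$variant_class) / 1000
  for (cl in names(cfg$variant_class_proportions)) {
    expect_lt(abs(vc[[cl]] - cfg$variant_class_proportions[[cl]]), 0.04,
              label = cl)
  }
})

test_that("nonsense sites show NMD in RNA but balanced DNA", {
  cfg <- sim_config(n_sites = 400, seed = 31, tissue_ids = paste0("t", 1:4))
  ds <- simulate_dataset(cfg)
  nonsense <- ds$truth$variant_class == "nonsense"
  mu_rna <- purrr::map_dbl(ds$truth$mu[nonsense], mean)
  expect_true(all(mu_rna < 0.45))
  dna <- dplyr::filter(ds$counts, assay == "exome_dna",
                       site_id %in% ds$truth$site_id[nonsense])
  ratio <- with(dna, alt_count / (ref_count + alt_count))
  expect_lt(abs(mean(ratio, na.rm = TRUE) - 0.5), 0.05)
  # DNA comes from exactly two samples
  expect_equal(length(unique(dna$tissue_id)), 2L)
})

test_that("fixtures round-trip through the package readers byte-identically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- sim_config(n_sites = 30, seed = 17, tissue_ids = paste0("t", 1:3))
  p1 <- end_to_end_fixture(cfg, dir1)
  p2 <- end_to_end_fixture(cfg, dir2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }

  sites_vcf <- read_het_sites(p1[["vcf"]], p1[["annotation"]])
  sites_tsv <- read_site_table(p1[["sites"]])
  expect_equal(nrow(sites_vcf), 30)
  expect_equal(sites_vcf$variant_class, sites_tsv$variant_class)
  counts <- read_count_table(p1[["counts_mmpcr"]])
  expect_equal(sort(unique(counts$tissue_id)), paste0("t", 1:3))
})

test_that("class recovery labels monoallelic sites ahead of shared geometry", {
  cfg <- sim_config(n_sites = 300, seed = 47,
                    class_proportions = c(no_ase = 0.25, shared_ase = 0.25,
                                          variable_ase = 0.25,
                                          monoallelic = 0.25),
                    variant_class_proportions = c(control = 1,
                                                  deleterious_nsSNP = 0,
                                                  nonsense = 0))
  ds <- simulate_dataset(cfg)
  mm <- merge_replicates(dplyr::filter(ds$counts, assay == "mmpcr"))
  bias <- estimate_reference_bias(mm)
  prof <- classify_profiles(build_profiles(call_ase(mm, ds$sites, bias)))
  rec <- class_recovery(prof, ds$truth)
  # monoallelic sites satisfy the shared-ASE geometry; detection must claim
  # them first and never the other way round
  confusion <- rec |> dplyr::count(true_class, predicted_class)
  expect_equal(sum(confusion$n[confusion$true_class == "monoallelic" &
                                 confusion$predicted_class == "shared_ase"]),
               0)
  expect_equal(sum(confusion$n[confusion$true_class == "shared_ase" &
                                 confusion$predicted_class == "monoallelic"]),
               0)
  mono_acc <- rec |>
    dplyr::filter(true_class == "monoallelic") |>
    dplyr::summarise(acc = mean(correct))
  expect_gt(mono_acc$acc, 0.9)
  expect_gt(mean(rec$correct), 0.85)
})
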