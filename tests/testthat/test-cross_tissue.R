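calls_from_ratios <- function(ratios, p_values = NULL, site_id = "S001",
                              depth = 200) {
  p_values <- p_values %||% rep(1, length(ratios))
  tibble::tibble(
    site_id = site_id,
    tissue_id = paste0("t", seq_along(ratios)),
    assay = "mmpcr",
    allelic_ratio = ratios,
    p_value = p_values,
    qc_pass = TRUE,
    ref_count = round(depth * (1 - ratios)),
    alt_count = round(depth * ratios)
  )
}

test_that("profiles summarise qc-passing tissues with population sd", {
  prof <- build_profiles(calls_from_ratios(c(0.5, 0.5, 0.5)))
  expect_equal(prof$mean_ratio, 0.5)
  expect_equal(prof$ratio_dispersion, 0)

  prof <- build_profiles(calls_from_ratios(c(0.10, 0.85, 0.50, 0.15, 0.90)))
  expect_equal(prof$mean_ratio, 0.50)
  expect_equal(prof$ratio_dispersion, 0.3361547, tolerance = 1e-6)
  expect_equal(prof$n_tissues, 5L)
})

test_that("qc-failing tissues are excluded and duplicates rejected", {
  calls <- calls_from_ratios(c(0.5, 0.9, 0.5))
  calls$qc_pass[2] <- FALSE
  prof <- build_profiles(calls)
  expect_equal(prof$n_tissues, 2L)
  expect_equal(prof$mean_ratio, 0.5)

  dup <- dplyr::bind_rows(calls, calls[1, ])
  expect_error(build_profiles(dup), "duplicate tissue")
})

test_that("classification follows the mean/dispersion/significance rules", {
  classify1 <- function(ratios, p_values = NULL) {
    prof <- build_profiles(calls_from_ratios(ratios, p_values))
    classify_profiles(prof)$class_label
  }
  # balanced, low dispersion, no significance -> NO_ASE
  expect_equal(classify1(c(0.50, 0.52, 0.48, 0.51, 0.49)), "NO_ASE")
  # imbalanced, tight, significant -> SHARED_ASE
  expect_equal(classify1(c(0.20, 0.22, 0.18, 0.25, 0.21),
                         rep(1e-4, 5)), "SHARED_ASE")
  # high dispersion with significant tissues -> VARIABLE_ASE
  expect_equal(classify1(c(0.10, 0.85, 0.50, 0.15, 0.90),
                         c(1e-5, 1e-5, 1, 1e-5, 1)), "VARIABLE_ASE")
  # imbalanced but never significant -> UNCLASSIFIED
  expect_equal(classify1(c(0.20, 0.22, 0.18, 0.25, 0.21)), "UNCLASSIFIED")
  # below the tissue minimum -> UNCLASSIFIED
  expect_equal(classify1(c(0.2, 0.2)), "UNCLASSIFIED")
})

test_that("boundary ties with any cutoff stay unclassified", {
  # mean exactly at ratio_lo, zero dispersion, significant
  prof <- make_profile(rep(0.35, 4), rep(1e-5, 4))
  expect_equal(classify_profiles(prof)$class_label, "UNCLASSIFIED")
  # dispersion exactly at the cutoff (pinned to dodge float rounding)
  prof <- make_profile(c(0.3, 0.7, 0.3, 0.7), rep(1e-5, 4))
  prof$ratio_dispersion <- 0.2
  expect_equal(classify_profiles(prof)$class_label, "UNCLASSIFIED")
})

test_that("classification is a deterministic partition of eligible profiles", {
  set.seed(17)
  profs <- dplyr::bind_rows(lapply(1:300, function(i) {
    nt <- sample(2:8, 1)
    make_profile(runif(nt), runif(nt), site_id = sprintf("S%03d", i))
  }))
  class(profs) <- c("ase_profiles", class(profs))
  out <- classify_profiles(profs)
  expect_equal(nrow(out), 300)
  expect_true(all(out$class_label %in%
                    c("NO_ASE", "SHARED_ASE", "VARIABLE_ASE", "UNCLASSIFIED")))
  expect_true(all(out$class_label[out$n_tissues < 3] == "UNCLASSIFIED"))
  expect_equal(sum(table(out$class_label)), 300)
})

test_that("monoallelic detection requires one extreme tail in all tissues", {
  mono <- detect_monoallelic(make_profile(c(0.98, 0.99, 1.0, 0.97, 0.96)))
  expect_equal(mono$expressed_allele, "alt")
  expect_true(mono$consistent)

  # direction flip is never monoallelic
  flip <- detect_monoallelic(make_profile(c(0.98, 0.02, 0.99, 0.97, 0.96)))
  expect_equal(nrow(flip), 0)

  # below the testable-tissue minimum
  few <- detect_monoallelic(make_profile(c(1, 1, 1, 1)))
  expect_equal(nrow(few), 0)

  ref_side <- detect_monoallelic(make_profile(c(0.01, 0.02, 0, 0.03, 0.05)))
  expect_equal(ref_side$expressed_allele, "ref")
})

test_that("monoallelic sites never span both tails (property)", {
  set.seed(23)
  n_reported <- 0
  for (i in 1:150) {
    # mix extreme-tail, both-tail and diffuse profiles
    r <- switch(1 + i %% 3,
                runif(6, 0.95, 1),
                sample(c(runif(3, 0, 0.05), runif(3, 0.95, 1))),
                runif(6))
    res <- detect_monoallelic(make_profile(r), min_testable = 5)
    if (nrow(res) == 1) {
      n_reported <- n_reported + 1
      expect_true(all(r >= 0.95) || all(r <= 0.05))
    } else {
      expect_false(all(r >= 0.95) || all(r <= 0.05))
    }
  }
  expect_gt(n_reported, 0)
})

test_that("ratio ranges and flip classes use the printed thresholds", {
  rr <- function(ratios) ratio_range_summary(make_profile(ratios))$flip_class
  expect_equal(rr(c(0.15, 0.85, 0.5)), "major")
  expect_equal(rr(c(0.35, 0.85, 0.5)), "large")
  expect_equal(rr(c(0.15, 0.65, 0.5)), "moderate")
  expect_equal(rr(c(0.45, 0.5, 0.55)), "none")
  # most extreme class wins: qualifies for major, not reported as large
  expect_equal(rr(c(0.1, 0.9, 0.5)), "major")
  # below three tissues -> not summarised
  expect_equal(nrow(ratio_range_summary(make_profile(c(0.1, 0.9)))), 0)
})

test_that("pairwise correlations recover known structure", {
  set.seed(41)
  x <- rnorm(200)
  mat <- cbind(a = x, b = x, c = -x + rnorm(200, sd = 1e-9))
  res <- pairwise_correlations(mat, method = "spearman")
  expect_equal(res$cor["a", "b"], 1)
  expect_equal(res$cor["a", "c"], -1)
  expect_equal(diag(res$cor), c(a = 1, b = 1, c = 1))
  expect_true(isSymmetric(res$cor))
})

test_that("spearman recovers a latent rank correlation of 0.8", {
  set.seed(61)
  n <- 2000
  # gaussian copula: pearson rho chosen so the spearman correlation is 0.8
  rho <- 2 * sin(0.8 * pi / 6)
  z <- matrix(rnorm(2 * n), ncol = 2)
  y2 <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  res <- pairwise_correlations(cbind(a = z[, 1], b = y2), "spearman")
  expect_lt(abs(res$cor["a", "b"] - 0.8), 0.03)
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(71)
  mat <- matrix(rlnorm(300), ncol = 3,
                dimnames = list(NULL, c("a", "b", "c")))
  r1 <- pairwise_correlations(mat, "spearman")$cor
  mat2 <- cbind(a = exp(mat[, "a"]), b = log(mat[, "b"]),
                c = mat[, "c"]^3)
  r2 <- pairwise_correlations(mat2, "spearman")$cor
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("sparse column pairs yield NA with a warning", {
  mat <- cbind(a = c(1, 2, 3, 4), b = c(1, NA, NA, NA))
  expect_warning(res <- pairwise_correlations(mat, "pearson"), "< 3")
  expect_true(is.na(res$cor["a", "b"]))
})
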