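#' Assemble and validate a pipeline configuration
#'
#' Merges filter, classification and simulator parameters with file paths
#' into one validated configuration for [run_pipeline()]. Unknown keys are
#' rejected so typos fail loudly rather than silently falling back to
#' defaults.
#'
#' @param out_dir Directory for stage outputs.
#' @param assay Assay whose counts flow through the calling stages
#'   (default `"mmpcr"`).
#' @param filter A [filter_params()] object or a list of overrides.
#' @param classify A [class_params()] object or a list of overrides.
#' @param sim A [sim_config()] object or a list of overrides; used when no
#'   external count table is supplied.
#' @param counts_path,sites_path Optional paths to existing count and site
#'   TSVs; when absent, the simulator generates them.
#' @param bias_scope `"sample"` or `"global"` (see
#'   [estimate_reference_bias()]).
#' @param seed Integer seed forwarded to the simulator.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            assay = "mmpcr",
                            filter = filter_params(),
                            classify = class_params(),
                            sim = sim_config(),
                            counts_path = NULL,
                            sites_path = NULL,
                            bias_scope = "sample",
                            seed = 1L) {
  if (!assay %in% ASSAY_LEVELS) {
    abort(sprintf("unknown assay '%s'", assay))
  }
  if (!bias_scope %in% c("sample", "global")) {
    abort("bias_scope must be 'sample' or 'global'")
  }
  if (is.list(filter) && !inherits(filter, "filter_params")) {
    check_known_keys(filter, names(formals(filter_params)), "filter")
    filter <- do.call(filter_params, filter)
  }
  if (is.list(classify) && !inherits(classify, "class_params")) {
    check_known_keys(classify, names(formals(class_params)), "classify")
    classify <- do.call(class_params, classify)
  }
  if (is.list(sim) && !inherits(sim, "sim_config")) {
    check_known_keys(sim, names(formals(sim_config)), "sim")
    sim <- do.call(sim_config, modifyList(list(seed = seed), sim))
  }
  structure(list(out_dir = out_dir, assay = assay, filter = filter,
                 classify = classify, sim = sim,
                 counts_path = counts_path, sites_path = sites_path,
                 bias_scope = bias_scope, seed = seed),
            class = "pipeline_config")
}

check_known_keys <- function(x, known, what) {
  bad <- setdiff(names(x), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown %s key(s): %s", what, paste(bad, collapse = ", ")))
  }
}

#' Run the full ASE pipeline and write its stage artifacts
#'
#' Orchestrates the stages in order — counts (simulated or loaded) →
#' replicate merge → bias estimation → per-site per-tissue ASE calls →
#' cross-tissue profiles and classification → monoallelic, ratio-range,
#' replicate-concordance and enrichment reports — writing each stage as a
#' TSV under `config$out_dir` plus a JSON run log (package version, seed,
#' per-stage site counts). Outputs are pure functions of (inputs, config,
#' seed): rerunning with unchanged inputs reproduces them byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages (default FALSE).
#' @return A list with the in-memory stage results (`sites`, `counts`,
#'   `merged`, `bias`, `calls`, `profiles`, `concordance`, `monoallelic`,
#'   `ratio_ranges`, `enrichment`) and `paths` of written files.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  paths <- list()

  if (is.null(config$counts_path)) {
    ds <- simulate_dataset(config$sim)
    sites <- ds$sites
    counts <- dplyr::filter(ds$counts, .data$assay == .env$config$assay)
    say("simulate: %d sites, %d count records", nrow(sites), nrow(counts))
  } else {
    counts <- read_count_table(config$counts_path)
    counts <- dplyr::filter(counts, .data$assay == .env$config$assay)
    if (is.null(config$sites_path)) {
      abort("counts_path given without sites_path: run the site stage first")
    }
    sites <- read_site_table(config$sites_path)
    say("load: %d sites, %d count records", nrow(sites), nrow(counts))
  }
  paths$counts <- file.path(config$out_dir, "counts.tsv")
  write_count_table(counts, paths$counts)
  paths$sites <- file.path(config$out_dir, "sites.tsv")
  write_site_table(sites, paths$sites)

  merged <- merge_replicates(counts)
  paths$merged <- file.path(config$out_dir, "counts_merged.tsv")
  write_count_table(merged, paths$merged)

  bias <- estimate_reference_bias(merged, scope = config$bias_scope,
                                  params = config$filter)
  paths$bias <- file.path(config$out_dir, "bias.tsv")
  readr::write_tsv(tidy(bias), paths$bias)
  say("bias: %d estimate(s), mean p_ref_hat %.4f", nrow(bias),
      mean(bias$p_ref_hat))

  calls <- call_ase(merged, sites, bias, config$filter)
  paths$calls <- file.path(config$out_dir, "ase_calls.tsv")
  write_ase_table(calls, paths$calls)
  say("call: %d calls, %d qc-pass, %d significant ASE",
      nrow(calls), sum(calls$qc_pass), sum(calls$is_ase))

  profiles <- build_profiles(calls,
                             min_tissues = config$classify$min_tissues) |>
    classify_profiles(config$classify)
  paths$profiles <- file.path(config$out_dir, "profiles.tsv")
  readr::write_tsv(flatten_profiles(profiles), paths$profiles)
  say("classify: %s",
      paste(sprintf("%s=%d", names(table(profiles$class_label)),
                    as.integer(table(profiles$class_label))),
            collapse = " "))

  mono <- detect_monoallelic(profiles)
  paths$monoallelic <- file.path(config$out_dir, "monoallelic.tsv")
  readr::write_tsv(mono, paths$monoallelic)

  ranges <- ratio_range_summary(profiles)
  paths$ratio_ranges <- file.path(config$out_dir, "ratio_ranges.tsv")
  readr::write_tsv(ranges, paths$ratio_ranges)

  concordance <- NULL
  reps <- unique(counts$replicate_id)
  if (length(reps) >= 2) {
    c1 <- call_ase(dplyr::filter(counts, .data$replicate_id == reps[1]),
                   sites, bias, config$filter)
    c2 <- call_ase(dplyr::filter(counts, .data$replicate_id == reps[2]),
                   sites, bias, config$filter)
    concordance <- replicate_concordance(c1, c2)
    paths$concordance <- file.path(config$out_dir, "concordance.tsv")
    readr::write_tsv(dplyr::select(concordance, -"by_depth"),
                     paths$concordance)
  }

  enrichment <- tryCatch(
    fisher_enrichment(profiles, sites),
    error = function(e) NULL
  )
  if (!is.null(enrichment)) {
    paths$enrichment <- file.path(config$out_dir, "enrichment.tsv")
    readr::write_tsv(tidy(enrichment), paths$enrichment)
  }

  log <- list(
    package = "tissueASE",
    version = as.character(utils::packageVersion("tissueASE")),
    seed = config$seed,
    assay = config$assay,
    n_sites = nrow(sites),
    n_counts = nrow(counts),
    n_qc_pass = sum(calls$qc_pass),
    n_ase = sum(calls$is_ase),
    class_counts = as.list(table(profiles$class_label))
  )
  paths$run_log <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(log, paths$run_log, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(sites = sites, counts = counts, merged = merged,
                 bias = bias, calls = calls, profiles = profiles,
                 concordance = concordance, monoallelic = mono,
                 ratio_ranges = ranges, enrichment = enrichment,
                 paths = paths))
}

# profiles with per-tissue ratio columns for TSV output
flatten_profiles <- function(profiles) {
  wide <- purrr::map2_dfr(profiles$site_id, profiles$ratios, function(id, r) {
    tibble::tibble(site_id = id, tissue_id = names(r), ratio = unname(r))
  }) |>
    tidyr::pivot_wider(names_from = "tissue_id", values_from = "ratio",
                       names_prefix = "ratio_")
  profiles |>
    dplyr::select("site_id", "n_tissues", "mean_ratio", "ratio_dispersion",
                  dplyr::any_of("n_significant"), "class_label") |>
    dplyr::left_join(wide, by = "site_id")
}
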