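# Derive per-stage seeds from one master seed so that every stage draws
# from an independent, reproducible stream.
derive_seeds <- function(master, n) {
  old <- local_seed(master)
  on.exit(restore_seed(old))
  sample.int(.Machine$integer.max - 1L, n)
}

load_cohort_block <- function(block, stage_seed) {
  if (!is.null(block$simulate)) {
    args <- block$simulate
    preset <- args$preset
    args$preset <- NULL
    if (is.null(args$seed)) args$seed <- stage_seed
    cfg <- if (!is.null(preset)) do.call(cpm_preset, c(list(preset), args))
           else do.call(cpm_sim_config, args)
    simulate_cohort(cfg)
  } else if (!is.null(block$edges) && !is.null(block$phenotypes)) {
    align_cohort(read_edge_matrix(block$edges),
                 read_phenotypes(block$phenotypes),
                 mean_fd_max = block$mean_fd_max)
  } else {
    stopf("cohort block must contain either 'simulate' or 'edges' + 'phenotypes'")
  }
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s (partial outputs are preserved)", name,
          conditionMessage(e)))
}

#' Run the full discovery-validation-characterization study
#'
#' Orchestrates the complete pipeline on one config: build (or load) the
#' discovery cohort, fit the cross-validated CPM with permutation testing,
#' derive the consensus network, evaluate it in an extension cohort if one
#' is configured, characterize it against the canonical networks, and write
#' every stage's outputs plus a reproducibility manifest to `out_dir`.
#'
#' @param config a list, or path to a YAML file, with elements `discovery`
#'   (either `simulate:` arguments — optionally with a `preset` name — or
#'   `edges`/`phenotypes` file paths), optional `extension` (same shape),
#'   and `cv` (arguments for [cpm()]). A `parcellation` path may be given;
#'   otherwise a synthetic parcellation matching the region count is used
#'   for characterization.
#' @param out_dir output directory (created if missing).
#' @param seed master seed; per-stage seeds are derived from it. Overrides
#'   `config$seed`.
#' @return Invisibly, a list with the fitted model, the extension result
#'   (or NULL), and the output paths.
#' @export
run_cpm_study <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) stopf("a master seed is required (config$seed or seed =)")
  seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 4L)
  t0 <- Sys.time()
  log_line <- function(fmt, ...) message(sprintf(paste0("[%s] ", fmt),
                                                 format(Sys.time(), "%H:%M:%S"),
                                                 ...))
  paths <- list()

  log_line("stage discovery-cohort")
  discovery <- run_stage("discovery-cohort",
                         load_cohort_block(config$discovery, seeds[1]))
  paths$phenotypes <- file.path(out_dir, "discovery_phenotypes.csv")
  write.csv(discovery$phenotypes, paths$phenotypes, row.names = FALSE)

  cv <- config$cv
  if (is.null(cv)) cv <- list()
  log_line("stage discover (CV + permutation)")
  fit <- run_stage("discover", do.call(cpm, c(list(cohort = discovery,
                                                   seed = seeds[2]), cv)))
  paths$cv_result <- file.path(out_dir, "cv_result.json")
  cvj <- list(mean_rho = fit$mean_rho, rhos = fit$rhos,
              n_zero_edge = fit$n_zero_edge,
              n_degenerate = fit$n_degenerate,
              settings = fit$settings, master_seed = seed)
  if (!is.null(fit$permutation)) {
    cvj$p_perm <- fit$permutation$p_perm
    cvj$n_permutations <- fit$permutation$n_permutations
    paths$null_rhos <- file.path(out_dir, "permutation_null.csv")
    write.csv(data.frame(permutation = seq_along(fit$permutation$null_rhos),
                         mean_rho = fit$permutation$null_rhos),
              paths$null_rhos, row.names = FALSE)
  }
  jsonlite::write_json(cvj, paths$cv_result, auto_unbox = TRUE, digits = NA,
                       na = "null")
  paths$network <- file.path(out_dir, "network_mask.csv")
  write_network_mask(fit$consensus, paths$network)

  ext_res <- NULL
  if (!is.null(config$extension)) {
    log_line("stage extension")
    ext_res <- run_stage("extension", {
      extension <- load_cohort_block(config$extension, seeds[3])
      strengths <- apply_network(fit$consensus, extension)
      calib <- if (isTRUE(config$use_discovery_calibration))
        fit$strength_model else NULL
      evaluate_extension(strengths, extension, calibration = calib)
    })
    paths$extension <- file.path(out_dir, "extension_result.json")
    jsonlite::write_json(unclass(ext_res), paths$extension, auto_unbox = TRUE,
                         digits = NA)
  }

  log_line("stage characterize")
  run_stage("characterize", {
    parc <- if (!is.null(config$parcellation))
      read_parcellation(config$parcellation)
    else make_parcellation(discovery$n_regions)
    paths$pair_counts <- file.path(out_dir, "pair_counts.csv")
    write.csv(pair_counts(fit$consensus, parc), paths$pair_counts,
              row.names = FALSE)
    paths$degree <- file.path(out_dir, "region_degree.csv")
    write.csv(region_degree(fit$consensus, parc), paths$degree,
              row.names = FALSE)
    paths$fc_profiles <- file.path(out_dir, "fc_profiles.csv")
    write.csv(fc_profiles(discovery, fit$consensus, parc), paths$fc_profiles,
              row.names = FALSE)
  })

  manifest <- list(
    master_seed = seed,
    stage_seeds = seeds,
    config = config,
    package_version = as.character(packageVersion("cpmnet")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    output_digests = as.list(tools::md5sum(unlist(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line("done")
  invisible(list(fit = fit, extension = ext_res, paths = paths))
}
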