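# Config-driven end-to-end runner: (simulate | read) -> normalize -> qc ->
# variance -> network -> integrate, with a machine-readable run report.

valid_config_keys <- c("seed", "out_dir", "input", "simulate",
                       "rsd_threshold", "max_missing", "k", "n_rotations",
                       "aggregation", "moderation", "edge_threshold")

#' Default pipeline configuration
#'
#' @param seed Master seed; per-stage seeds are derived from it by fixed
#'   offsets so stages are individually reproducible.
#' @param out_dir Output directory.
#' @return A named list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1, out_dir = "fecanet_out") {
  list(seed = seed, out_dir = out_dir, simulate = list(),
       rsd_threshold = 30, max_missing = 0.20, k = 10,
       n_rotations = 50, aggregation = "participant_mean",
       moderation = "empirical_bayes", edge_threshold = 1e-8)
}

load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  bad <- setdiff(names(config), valid_config_keys)
  if (length(bad))
    stopf("invalid config key(s): %s (valid keys: %s)",
          paste(bad, collapse = ", "),
          paste(valid_config_keys, collapse = ", "))
  cfg <- default_config()
  cfg[names(config)] <- config
  if (!is.null(config$input)) cfg$simulate <- NULL
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (either [simulate_study()] from the
#' `simulate` config block, or [read_feature_table()] from the `input`
#' block with `peak`/`samples`/`features` paths), internal-standard
#' normalization, the QC gate (unknowns, pool-RSD, missingness, kNN
#' imputation), the variance decomposition with moderated F-tests, the
#' partial-correlation network, and the category integration matrix. All
#' stage outputs are written under `out_dir`, together with
#' `run_report.json` recording every parameter, the stage-by-stage feature
#' counts and the derived seeds. Outputs are byte-identical across reruns
#' with the same config; stage timings go to the log stream only.
#'
#' @param config A named list or path to a YAML file. Valid keys: `seed`,
#'   `out_dir`, `input`, `simulate`, `rsd_threshold`, `max_missing`, `k`,
#'   `n_rotations`, `aggregation`, `moderation`, `edge_threshold`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the run report, the final tables and the
#'   network model.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  cfg <- load_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf("[fecanet %s] %s", format(Sys.time(), "%H:%M:%S"),
                                sprintf(fmt, ...)))
  }
  t0 <- Sys.time()
  seeds <- list(simulate = derive_seed(cfg$seed, 101),
                network = derive_seed(cfg$seed, 202))

  # ---- acquire --------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$input)) {
    say("reading peak table from %s", cfg$input$peak)
    tab <- read_feature_table(cfg$input$peak, cfg$input$samples,
                              cfg$input$features)
    tab <- record_stage(tab, "input", nrow(tab$intensities),
                        nrow(tab$intensities))
  } else {
    sim_args <- cfg$simulate
    sim_args$seed <- NULL                 # the master seed governs all stages
    sim_cfg <- do.call(simulation_config,
                       c(sim_args, list(seed = seeds$simulate)))
    say("simulating study (%d participants x %d areas, %d features)",
        sim_cfg$n_participants, sim_cfg$n_areas,
        sim_cfg$n_polar + sim_cfg$n_lipid + sim_cfg$n_unknowns +
          2L * sim_cfg$n_is_per_platform)
    sim <- simulate_study(sim_cfg)
    tab <- sim$table
    truth <- sim$truth
    write_feature_table(tab, file.path(out_dir, "simulated"))
    write_truth(truth, file.path(out_dir, "truth.json"))
  }

  # ---- normalize ------------------------------------------------------------
  say("internal-standard normalization")
  tab <- normalize_to_is(tab)
  map <- attr(tab, "is_mapping")
  map$r <- format_full(map$r)
  utils::write.table(map, file.path(out_dir, "is_mapping.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- qc -------------------------------------------------------------------
  say("QC gate (unknowns -> pool RSD %g%% -> missingness %g -> impute k=%d)",
      cfg$rsd_threshold, cfg$max_missing, cfg$k)
  tab <- filter_unknowns(tab)
  tab <- filter_by_pool_rsd(tab, threshold = cfg$rsd_threshold)
  tab <- filter_by_missingness(tab, max_fraction = cfg$max_missing)
  if (nrow(tab$intensities) == 0)
    stopf("QC removed every feature; nothing to analyze")
  tab <- knn_impute(tab, k = cfg$k)
  write_feature_table(tab, file.path(out_dir, "qc"))

  # ---- variance -------------------------------------------------------------
  say("variance decomposition + F-tests (%d features)", nrow(tab$intensities))
  profile <- variance_profile(tab, moderation = cfg$moderation)
  write_variance_profile(profile, out_dir)

  # ---- network --------------------------------------------------------------
  say("network inference (aggregation: %s)", cfg$aggregation)
  model <- infer_network(tab, level = cfg$aggregation, seed = seeds$network,
                         n_rotations = cfg$n_rotations,
                         edge_threshold = cfg$edge_threshold)
  write_network(model, out_dir)

  # ---- integrate ------------------------------------------------------------
  say("category integration")
  heat <- integration_matrix(tab)
  write_integration_matrix(heat, file.path(out_dir, "heatmap_matrix.tsv"))

  # ---- report ---------------------------------------------------------------
  # out_dir is a location, not an analysis parameter: leaving it out keeps
  # the report byte-identical across reruns into different directories
  report <- list(
    parameters = cfg[setdiff(names(cfg), c("input", "simulate", "out_dir"))],
    simulate = if (is.null(cfg$input)) truth$config else NULL,
    input = cfg$input,
    seeds = seeds,
    stage_counts = stage_counts(tab),
    n_samples = ncol(tab$intensities),
    network = list(lambda = model$lambda, hub = model$hub,
                   n_edges = nrow(model$edges),
                   converged = isTRUE(model$converged)))
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  say("done in %.1f s; outputs in %s",
      as.numeric(difftime(Sys.time(), t0, units = "secs")), out_dir)
  invisible(list(report = report, table = tab, profile = profile,
                 network = model, integration = heat, truth = truth))
}

# Serialize simulation truth (matrices as nested lists) to JSON.
write_truth <- function(truth, path) {
  tr <- truth
  tr$true_precision <- unname(apply(tr$true_precision, 1, as.list))
  tr$true_covariance <- NULL
  tr$mu <- NULL
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
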