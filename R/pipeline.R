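# End-to-end orchestration: simulate (or read) -> normalize -> fit ->
# compare -> variability -> classify -> cluster, with a manifest recording
# every parameter used.

#' Assemble a pipeline configuration
#'
#' Defaults match the printed constants of the analysis: significance level
#' 0.05, EC50 fold gate 3, margin threshold 20, sigmoid bottom 0 and Hill
#' coefficient -1 (both built into the model itself).
#'
#' @param scenario Name of a preset scenario ([preset_scenarios()]), used
#'   when `wells_path` is `NULL`.
#' @param wells_path Optional CSV of measured wells to analyze instead of
#'   simulating.
#' @param seed Integer seed; the single source of randomness.
#' @param fit Fit options ([fit_options()]).
#' @param alpha,fold_gate Dual-rule constants.
#' @param threshold Margin-of-safety classification threshold.
#' @param sweep Threshold grid for the sensitivity/specificity sweep.
#' @param strata Variability strata to evaluate.
#' @param cluster_endpoint,cluster_time,cluster_metric,impute_policy
#'   Clustering slice and options.
#' @param out_dir Output directory for the CSV/Newick/manifest bundle.
#' @return Named configuration list for [run_pipeline()].
#' @export
run_config <- function(scenario = "default", wells_path = NULL, seed = 1L,
                       fit = fit_options(), alpha = 0.05, fold_gate = 3,
                       threshold = 20, sweep = c(1, 2, 5, 10, 20, 50, 100),
                       strata = c("inter_lab", "intra_lab"),
                       cluster_endpoint = "ATP", cluster_time = 72,
                       cluster_metric = "euclidean",
                       impute_policy = "drop_row",
                       out_dir = tempfile("cytotoxpanel_run_")) {
  list(scenario = scenario, wells_path = wells_path, seed = as.integer(seed),
       fit = fit, alpha = alpha, fold_gate = fold_gate,
       threshold = threshold, sweep = sweep, strata = strata,
       cluster_endpoint = cluster_endpoint, cluster_time = cluster_time,
       cluster_metric = cluster_metric, impute_policy = impute_policy,
       out_dir = out_dir)
}

#' Run the full analysis pipeline
#'
#' Chains simulation (or reading), vehicle normalization, constrained
#' sigmoid fitting, pairwise curve comparison per stratum, variability
#' coefficients, margin-of-safety classification with threshold sweep, and
#' hierarchical clustering. Writes `wells.csv`, `fits.csv`,
#' `comparisons.csv`, `variability.csv`, `margins.csv`, `sweep.csv`,
#' `tree.nwk` and `manifest.json` into `config$out_dir`. Deterministic:
#' the same configuration (including seed) reproduces the bundle exactly.
#'
#' @param config Configuration from [run_config()].
#' @param panel Compound panel ([load_panel()]).
#' @return Invisible list with all intermediate tables and the manifest.
#' @export
run_pipeline <- function(config = run_config(), panel = load_panel()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, n_in, n_out) {
    message(sprintf("[%s] %s: %d records in, %d out", "cytotoxpanel",
                    stage, n_in, n_out))
  }

  if (is.null(config$wells_path)) {
    sc <- preset_scenarios(panel)[[config$scenario]]
    if (is.null(sc)) stop("unknown scenario: ", config$scenario,
                          call. = FALSE)
    sim <- generate_dataset(panel, sc$design, sc$params, seed = config$seed)
    wells <- sim$wells
    truth <- sim$truth
  } else {
    wells <- read_wells(config$wells_path)
    truth <- NULL
  }
  write_wells(wells, file.path(config$out_dir, "wells.csv"))
  log_stage("input", nrow(wells), nrow(wells))

  series <- normalize_to_vehicle(wells)
  log_stage("normalize", nrow(wells), nrow(series))

  fits <- fit_all(series, config$fit)
  log_stage("fit", nrow(series), nrow(fits))
  utils::write.csv(as.data.frame(fits),
                   file.path(config$out_dir, "fits.csv"), row.names = FALSE)

  comparisons <- list()
  reports <- list()
  for (st in config$strata) {
    pairs <- withCallingHandlers(
      enumerate_pairs(fits, st),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(pairs) == 0) next
    cmp <- compare_pairs(series, pairs, config$fit,
                         alpha = config$alpha, fold_gate = config$fold_gate)
    comparisons[[st]] <- dplyr::bind_cols(
      tibble::tibble(stratum = rep(st, nrow(cmp))), cmp)
    reports[[st]] <- variability_coefficient(cmp, stratum = st)
  }
  comparisons <- dplyr::bind_rows(comparisons)
  variability <- dplyr::bind_rows(reports)
  log_stage("compare", nrow(fits), nrow(comparisons))
  utils::write.csv(as.data.frame(comparisons),
                   file.path(config$out_dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(variability),
                   file.path(config$out_dir, "variability.csv"),
                   row.names = FALSE)

  agg <- aggregate_ec50(fits)
  margins <- classify_margins(compute_margins(agg, panel), config$threshold)
  sweep <- threshold_sweep(
    compute_margins(
      aggregate_ec50(fits[fits$endpoint == config$cluster_endpoint &
                            fits$exposure_h == config$cluster_time, ]),
      panel),
    config$sweep)
  log_stage("classify", nrow(agg), nrow(margins))
  utils::write.csv(as.data.frame(margins),
                   file.path(config$out_dir, "margins.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sweep),
                   file.path(config$out_dir, "sweep.csv"), row.names = FALSE)

  m <- build_ec50_matrix(fits, endpoint = config$cluster_endpoint,
                         exposure_h = config$cluster_time)
  m <- impute_missing(m, config$impute_policy, panel)
  clustering <- NULL
  if (nrow(m) >= 2 && ncol(m) >= 2) {
    clustering <- withCallingHandlers(
      cluster_models(m, config$cluster_metric),
      warning = function(w) invokeRestart("muffleWarning"))
    writeLines(clustering$newick, file.path(config$out_dir, "tree.nwk"))
  }
  log_stage("cluster", length(m), if (is.null(clustering)) 0L else
    length(clustering$hclust$order))

  manifest <- list(
    package = "cytotoxpanel",
    version = as.character(utils::packageVersion("cytotoxpanel")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    n_wells = nrow(wells), n_series_points = nrow(series),
    n_fits = nrow(fits), n_comparisons = nrow(comparisons))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(wells = wells, truth = truth, series = series, fits = fits,
                 comparisons = comparisons, variability = variability,
                 margins = margins, sweep = sweep, matrix = m,
                 clustering = clustering, manifest = manifest))
}
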