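#' Declarative configuration for a strategy-comparison experiment
#'
#' Bundles every setting of the generate/run/report pipeline in one object
#' that serializes losslessly to YAML, so a large experiment cross product is
#' restartable and auditable from a single file.  The defaults reproduce the
#' conventional study setup: search box `log10(C) in [-2, 5]`,
#' `log10(gamma) in [-10, 3]`, budget set `{20, 30, 50, 75, 100, 150}`, all
#' six strategies, and a 5-fold CV objective.
#'
#' @param space A [search_space()].
#' @param budgets Integer vector of evaluation budgets.
#' @param strategies Named list of per-strategy settings (see [run_suite()]).
#' @param n_folds,fold_seed CV objective settings.
#' @param seeds Replicate seeds for stochastic strategies.
#' @param n_targets,fingerprint_specs,size_range,effect_range Synthetic
#'   suite description (see [make_benchmark_suite()]).
#' @param suite_seed Seed for suite generation.
#' @param out_dir Output directory for datasets, traces, and reports.
#' @return An object of class `run_config`.
#' @export
run_config <- function(space = default_search_space(),
                       budgets = c(20L, 30L, 50L, 75L, 100L, 150L),
                       strategies = list(bayes = list(init_count = 5L),
                                         random = list(),
                                         grid = list(M_C = 14L, M_gamma = 14L),
                                         small_grid = list(),
                                         libsvm = list(),
                                         svmlight = list()),
                       n_folds = 5L, fold_seed = 1L, seeds = 1L,
                       n_targets = 10L,
                       fingerprint_specs = list(
                         fingerprint_spec(79L, 0.1, 8L, 0.3, name = "fp079"),
                         fingerprint_spec(166L, 0.1, 16L, 0.3, name = "fp166")),
                       size_range = c(30L, 80L),
                       effect_range = c(0.15, 0.6),
                       suite_seed = 1L,
                       out_dir = "svmtune_output") {
  stopifnot(inherits(space, "search_space"), length(budgets) >= 1L,
            length(strategies) >= 1L)
  structure(list(space = space, budgets = as.integer(budgets),
                 strategies = strategies, n_folds = as.integer(n_folds),
                 fold_seed = as.integer(fold_seed), seeds = as.integer(seeds),
                 n_targets = as.integer(n_targets),
                 fingerprint_specs = fingerprint_specs,
                 size_range = as.integer(size_range),
                 effect_range = as.numeric(effect_range),
                 suite_seed = as.integer(suite_seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read and write pipeline configurations as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` invisibly returns `path`;
#'   `read_run_config()` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$space <- unclass(x$space)
  x$fingerprint_specs <- lapply(x$fingerprint_specs, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(
    space = do.call(search_space, x$space),
    budgets = x$budgets,
    strategies = lapply(x$strategies, function(s) s %||% list()),
    n_folds = x$n_folds, fold_seed = x$fold_seed, seeds = x$seeds,
    n_targets = x$n_targets,
    fingerprint_specs = lapply(x$fingerprint_specs,
                               function(s) do.call(fingerprint_spec, s)),
    size_range = x$size_range, effect_range = x$effect_range,
    suite_seed = x$suite_seed, out_dir = x$out_dir)
}

#' Generate, run, and report a configured experiment
#'
#' The three pipeline stages behind one [run_config()]:
#'
#' * `pipeline_generate()` materializes the synthetic benchmark suite as CSV
#'   files plus a JSON manifest under `<out_dir>/datasets`; idempotent under
#'   a fixed `suite_seed`.
#' * `pipeline_run()` executes [run_suite()] over the manifest, streaming
#'   trace files to `<out_dir>/traces` (existing traces are reused, so an
#'   interrupted run resumes) and writing per-cell summaries to
#'   `<out_dir>/results.csv`.
#' * `pipeline_report()` writes win-count and mean-AUC/final-accuracy tables
#'   (overall, by fingerprint, by target) as CSVs under
#'   `<out_dir>/report`.
#'
#' All outputs are plain text without timestamps, so a rerun under one
#' configuration is byte-identical.
#'
#' @param config A [run_config()].
#' @param strategies Optional character subset of configured strategy names
#'   to run (default: all).
#' @param verbose Print progress lines.
#' @return `pipeline_generate()` the manifest path; `pipeline_run()` the
#'   results data frame; `pipeline_report()` the report directory,
#'   invisibly.
#' @export
pipeline_generate <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  suite <- make_benchmark_suite(config$n_targets, config$fingerprint_specs,
                                size_range = config$size_range,
                                effect_range = config$effect_range,
                                seed = config$suite_seed)
  dir <- file.path(config$out_dir, "datasets")
  mpath <- write_suite(suite, dir)
  if (verbose)
    cat(sprintf("[generate] wrote %d datasets to %s\n", length(suite), dir))
  invisible(mpath)
}

#' @rdname pipeline_generate
#' @export
pipeline_run <- function(config, strategies = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir <- file.path(config$out_dir, "datasets")
  if (!file.exists(file.path(dir, "manifest.json")))
    stop("no dataset manifest under ", dir,
         "; run pipeline_generate() first", call. = FALSE)
  suite <- read_suite(dir)
  strat_cfg <- config$strategies
  if (!is.null(strategies)) {
    bad <- setdiff(strategies, names(strat_cfg))
    if (length(bad))
      stop("unknown strategy name(s): ", paste(bad, collapse = ", "),
           "; configured strategies: ",
           paste(names(strat_cfg), collapse = ", "), call. = FALSE)
    strat_cfg <- strat_cfg[strategies]
  }
  res <- run_suite(suite, strat_cfg, budgets = config$budgets,
                   seeds = config$seeds, n_folds = config$n_folds,
                   fold_seed = config$fold_seed,
                   out_dir = file.path(config$out_dir, "traces"),
                   verbose = verbose)
  utils::write.csv(res, file.path(config$out_dir, "results.csv"),
                   row.names = FALSE, quote = FALSE)
  res
}

#' @rdname pipeline_generate
#' @export
pipeline_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rpath <- file.path(config$out_dir, "results.csv")
  if (!file.exists(rpath))
    stop("no results.csv under ", config$out_dir,
         "; run pipeline_run() first", call. = FALSE)
  res <- utils::read.csv(rpath)
  rep_dir <- file.path(config$out_dir, "report")
  if (!dir.exists(rep_dir)) dir.create(rep_dir, recursive = TRUE)
  top <- res[res$budget == max(res$budget), , drop = FALSE]
  wins <- count_wins(top)
  utils::write.csv(wins$overall, file.path(rep_dir, "wins_overall.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(wins$by_fingerprint,
                   file.path(rep_dir, "wins_by_fingerprint.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(wins$by_target, file.path(rep_dir, "wins_by_target.csv"),
                   row.names = FALSE, quote = FALSE)
  for (metric in c("auc", "final_value")) {
    f <- stats::as.formula(paste(metric, "~ strategy + budget"))
    utils::write.csv(stats::aggregate(f, res, mean),
                     file.path(rep_dir, paste0("mean_", metric, ".csv")),
                     row.names = FALSE, quote = FALSE)
    g <- stats::as.formula(paste(metric, "~ strategy + fingerprint"))
    utils::write.csv(
      stats::aggregate(g, res[res$budget == max(res$budget), ], mean),
      file.path(rep_dir, paste0("mean_", metric, "_by_fingerprint.csv")),
      row.names = FALSE, quote = FALSE)
  }
  invisible(rep_dir)
}
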