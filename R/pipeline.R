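#' @title End-to-end pipeline stages
#'
#' @description
#' The three stages of the analysis — generate a synthetic double-read
#' dataset, fit the reader model to records, simulate and compare pairing
#' strategies — each exposed as one function writing plain-text artifacts
#' (CSV tables, JSON sidecars and logs). `inst/cli/doubleread.R` is a thin
#' command-line wrapper over these.
#'
#' @name pipeline
NULL

# weak rolling hash of the deparsed config, for the reproducibility log only
config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x, control = "all"), collapse = "\n"))
  h <- 0
  for (ch in s) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_run_log <- function(out_dir, stage, seed, cfg, extra = list()) {
  log <- c(list(stage = stage,
                package_version = as.character(utils::packageVersion("doubleread")),
                master_seed = seed,
                config_hash = config_hash(cfg),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           extra)
  jsonlite::write_json(log, file.path(out_dir, paste0(stage, "_log.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read a run configuration from YAML
#'
#' Recognised top-level blocks mirror the stage configurations:
#' `population` ([population_config()] fields), `dataset`
#' ([dataset_config()] fields), `fit` (`f_tol`, `max_iterations`,
#' `mc_samples`, `min_positive_reads_per_pair`), `schedule`
#' ([schedule_config()] fields), plus `seed` and `out_dir`. Missing fields
#' take the package defaults.
#'
#' @param path YAML file.
#' @return Named list of config blocks.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  yaml::read_yaml(path)
}

apply_fields <- function(constructor, defaults, fields) {
  known <- names(formals(constructor))
  extra <- setdiff(names(fields), known)
  if (length(extra))
    stop_invalid("unknown config field(s): ", paste(extra, collapse = ", "))
  do.call(constructor, utils::modifyList(defaults, fields))
}

#' Generate stage: synthetic population and reading records
#'
#' @param pop Named list of [population_config()] fields (or a ready config).
#' @param dataset Named list of [dataset_config()] fields (needs `n_exams`).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed applied to both stage configs unless they carry
#'   their own.
#' @param verbose Print progress.
#' @return Invisibly, list with paths `records`, `truth` and the generated
#'   objects.
#' @export
run_generate <- function(pop = list(), dataset = list(), out_dir = ".",
                         seed = 1L, verbose = TRUE) {
  if (!inherits(pop, "population_config"))
    pop <- apply_fields(population_config, list(n_readers = 20L, seed = seed), pop)
  if (!inherits(dataset, "dataset_config"))
    dataset <- apply_fields(dataset_config, list(n_exams = 100000L, seed = seed),
                            dataset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_reader_population(pop)
  records <- generate_reading_records(gen$params, dataset)
  records_path <- file.path(out_dir, "records.csv")
  truth_path <- file.path(out_dir, "truth_params.csv")
  write_reading_records(records, records_path)
  write_model_parameters(gen$params, truth_path,
                         meta = list(kind = "synthetic_ground_truth",
                                     seed = pop$seed))
  write_run_log(out_dir, "generate", seed, list(pop = pop, dataset = dataset),
                extra = list(n_records = nrow(records)))
  if (verbose)
    message(sprintf("wrote %d records for %d exams (%d readers) to %s",
                    nrow(records), dataset$n_exams, pop$n_readers, records_path))
  invisible(list(records = records_path, truth = truth_path,
                 population = gen, data = records))
}

#' Fit stage: records in, fitted parameters and diagnostics out
#'
#' Reads records, applies the exclusion criteria (cascading, recomputed from
#' records), fits the reader model, and writes `fitted_params.csv` (+ JSON
#' sidecar with sigmas, NLL and settings) and `diagnostics.json` (the four
#' modeled-vs-observed Pearson correlations).
#'
#' @param records_path Reading-records CSV.
#' @param out_dir Output directory.
#' @param mc_samples Monte Carlo sample size for the fit (default 1e5).
#' @param f_tol Powell fractional tolerance (default 1e-4).
#' @param min_positive_reads_per_pair Exclusion threshold (default 17).
#' @param seed Seed for the Monte Carlo streams.
#' @param verbose Print progress.
#' @return Invisibly, list with the `fit`, `diagnostics` and output paths.
#' @export
run_fit <- function(records_path, out_dir = ".", mc_samples = 1e5,
                    f_tol = 1e-4, min_positive_reads_per_pair = 17L,
                    seed = 1L, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_reading_records(records_path)
  counts <- aggregate_reading_records(records)
  counts <- apply_exclusion_criteria(counts, min_positive_reads_per_pair,
                                     records = records)
  cfg <- fit_config(f_tol = f_tol, mc = mc_config(mc_samples, seed))
  fit <- fit_model(counts, cfg)
  diag <- evaluate_fit(fit, counts)
  params_path <- file.path(out_dir, "fitted_params.csv")
  write_model_parameters(fit$params, params_path,
                         meta = list(nll = fit$nll,
                                     nll_neg = unname(fit$nll_by_class["neg"]),
                                     nll_pos = unname(fit$nll_by_class["pos"]),
                                     mc_samples = mc_samples, f_tol = f_tol,
                                     seed = seed))
  diag_path <- file.path(out_dir, "diagnostics.json")
  jsonlite::write_json(as.list(unclass(diag)), diag_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_run_log(out_dir, "fit", seed, cfg,
                extra = list(n_readers = nrow(counts$readers),
                             n_pairs = nrow(counts$pairs), nll = fit$nll))
  if (verbose) {
    message(sprintf("fitted %d readers, %d pairs; NLL = %.2f",
                    nrow(counts$readers), nrow(counts$pairs), fit$nll))
    print(diag)
  }
  invisible(list(fit = fit, diagnostics = diag,
                 params = params_path, diagnostics_path = diag_path))
}

#' Simulate stage: pairing-strategy comparison
#'
#' Reads fitted (or ground-truth) parameters and writes one CSV row per
#' pairing strategy plus one for individual reading, with bootstrap CIs,
#' sampled TP/FP counts and RR/CDR.
#'
#' @param params_path Parameter CSV with JSON sidecar.
#' @param out_dir Output directory.
#' @param schedule Named list of [schedule_config()] fields (or a ready
#'   config).
#' @param n_boot Bootstrap resamples (default 1,000).
#' @param seed Master seed (used unless `schedule` carries its own).
#' @param verbose Print progress.
#' @return Invisibly, list with the results data frame and its path.
#' @export
run_simulate <- function(params_path, out_dir = ".", schedule = list(),
                         n_boot = 1000L, seed = 1L, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- read_model_parameters(params_path)
  if (!inherits(schedule, "schedule_config"))
    schedule <- apply_fields(schedule_config, list(seed = seed), schedule)
  results <- compare_pairing_strategies(params, schedule, n_boot = n_boot)
  results_path <- file.path(out_dir, "strategy_results.csv")
  write_strategy_results(results, results_path)
  write_run_log(out_dir, "simulate", seed, schedule,
                extra = list(n_exams = schedule$n_days * schedule$exams_per_day))
  if (verbose) {
    message(sprintf("simulated %d strategies on %s exams",
                    nrow(results),
                    format(schedule$n_days * schedule$exams_per_day,
                           big.mark = ",")))
    print(results[, c("strategy", "tpr", "fpr", "rr_per_1000", "cdr_per_1000")])
  }
  invisible(list(results = results, path = results_path))
}
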