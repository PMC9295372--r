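# End-to-end orchestration: simulate (or ingest) a cohort, NCA, group
# statistics, PCA, optimizer-initialized network training, evaluation and
# MIV, with every table written to an artifact directory.

#' Default pipeline configuration
#'
#' A plain list mirroring the module options; any subset can be overridden
#' via `run_pipeline(config = list(...))` or a YAML file with the same
#' field names (see [read_pipeline_config()]). `covariates` and `pk` take
#' argument lists for [covariate_spec()] / [pk_model_spec()];
#' `optimizer_config` a per-optimizer list of config overrides; `train` an
#' argument list for [lm_control()].
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(n_subjects = 47,
       seed = 101,
       times = sampling_schedule(),
       covariates = NULL,
       pk = NULL,
       pca_threshold = 90,
       split = c(0.70, 0.15, 0.15),
       hidden = 13,
       optimizers = "pso",
       optimizer_config = NULL,
       train = NULL)
}

#' Read a YAML pipeline configuration
#'
#' Fields mirror [default_config()]; missing fields keep their defaults.
#'
#' @param path YAML file.
#' @return merged configuration list.
#' @export
read_pipeline_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

#' Optimizer comparison table
#'
#' One row per optimizer with its test-split R^2, MAE and RMSE, sorted by
#' R^2 descending; the best row is flagged. The table reports — it does not
#' assert — which initializer won.
#'
#' @param results data.frame with columns `optimizer`, `r2`, `mae`, `rmse`
#'   (plus any metadata columns, carried through).
#' @return the table sorted by `r2` with a logical `best` column.
#' @export
compare_optimizers <- function(results) {
  if (!nrow(results)) stop("no evaluated models", call. = FALSE)
  out <- results[order(-results$r2), , drop = FALSE]
  out$best <- seq_len(nrow(out)) == 1L
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Cohort generation (or ingestion of `covariates.csv` /
#' `concentrations.csv`), NCA, group summaries and age/gender tests,
#' feature assembly, then — for each requested optimizer — PCA + network
#' fitting via [fit_conc_model()] (training-rows-only fitting of PCA and
#' normalizers), evaluation, and MIV on the best model. All named artifact
#' tables are written to `outdir` together with a JSON run log (package
#' version, resolved configuration, seeds).
#'
#' Seeds are derived from `config$seed`: cohort = seed, row split =
#' seed + 1, initial weights = seed + 2, optimizer i = seed + 10 + i. The
#' same configuration and seed reproduce every output byte for byte.
#'
#' @param config override list (see [default_config()]).
#' @param outdir artifact directory (created).
#' @param input optional list with paths `covariates` and `concentrations`
#'   to analyse user data instead of simulating.
#' @return invisibly, a list with the cohort, NCA table, group tables, the
#'   per-optimizer fits, the comparison table and the MIV table.
#' @export
run_pipeline <- function(config = list(), outdir, input = NULL) {
  cfg <- merge_config(default_config(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(input)) {
    cohort <- simulate_cohort(
      n_subjects = cfg$n_subjects,
      cov_spec = do.call(covariate_spec, cfg$covariates %||% list()),
      pk_spec = do.call(pk_model_spec, cfg$pk %||% list()),
      times = cfg$times, seed = cfg$seed)
  } else {
    cohort <- list(covariates = read_covariates(input$covariates),
                   concentrations = read_concentrations(input$concentrations))
  }
  write_cohort(cohort, outdir)

  nca <- nca_table(cohort$concentrations)
  write.csv(nca, file.path(outdir, "nca_results.csv"), row.names = FALSE)
  summary_tab <- summarize_groups(nca, cohort$covariates, format = TRUE)
  write.csv(cbind(parameter = rownames(summary_tab), summary_tab),
            file.path(outdir, "group_summary.csv"), row.names = FALSE)
  tests <- group_tests(nca, cohort$covariates)
  write.csv(tests, file.path(outdir, "group_tests.csv"), row.names = FALSE)

  features <- assemble_feature_table(cohort$covariates, cohort$concentrations)
  fits <- list()
  for (i in seq_along(cfg$optimizers)) {
    opt <- cfg$optimizers[i]
    fits[[opt]] <- fit_conc_model(
      features, hidden = cfg$hidden, pca_threshold = cfg$pca_threshold,
      split_ratios = cfg$split, optimizer = opt,
      opt_config = cfg$optimizer_config[[opt]],
      control = do.call(lm_control, cfg$train %||% list()),
      split_seed = cfg$seed + 1, init_seed = cfg$seed + 2,
      opt_seed = cfg$seed + 10 + i)
  }

  write.csv(pca_table(fits[[1L]]$model$pca), file.path(outdir, "pca_table.csv"),
            row.names = FALSE)
  traces <- do.call(rbind, lapply(names(fits), function(opt) {
    tr <- fits[[opt]]$trace
    if (is.null(tr)) return(NULL)
    data.frame(optimizer = opt, iteration = seq_along(tr), best_fitness = tr)
  }))
  if (!is.null(traces)) {
    write.csv(traces, file.path(outdir, "optimizer_trace.csv"), row.names = FALSE)
  }

  eval_rows <- do.call(rbind, lapply(names(fits), function(opt) {
    ev <- fits[[opt]]$evaluation
    te <- ev[ev$split == "test", ]
    cfg_used <- if (opt == "none") NULL else
      switch(opt, pso = pso_config(), woa = woa_config(), ga = ga_config())
    cfg_used <- merge_config(cfg_used %||% list(pop = NA, iters = NA),
                             cfg$optimizer_config[[opt]])
    budget <- if (opt == "none") NA_real_ else
      cfg_used$pop * (cfg_used$iters %||% cfg_used$gens)
    data.frame(optimizer = opt, r2 = te$r2, mae = te$mae, rmse = te$rmse,
               budget = budget)
  }))
  comparison <- compare_optimizers(eval_rows)
  write.csv(comparison, file.path(outdir, "optimizer_comparison.csv"),
            row.names = FALSE)

  winner <- comparison$optimizer[1L]
  best_fit <- fits[[winner]]
  miv <- miv_table(best_fit$model, features)
  write.csv(miv, file.path(outdir, "miv_table.csv"), row.names = FALSE)
  save_model(best_fit$model, file.path(outdir, "model.json"))

  report <- lapply(fits, function(f)
    c(f$report, list(paired_t = f$paired,
                     evaluation = f$evaluation)))
  jsonlite::write_json(report, file.path(outdir, "training_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("pkswarm")),
         config = cfg,
         seeds = list(cohort = cfg$seed, split = cfg$seed + 1,
                      init = cfg$seed + 2,
                      optimizers = cfg$seed + 10 + seq_along(cfg$optimizers)),
         winner = winner),
    file.path(outdir, "run_log.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, nca = nca, summary = summary_tab,
                 tests = tests, features = features, fits = fits,
                 comparison = comparison, miv = miv, outdir = outdir))
}
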