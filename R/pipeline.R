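#' Per-stage derived seeds
#'
#' One global seed fans out to per-stage seeds (a stable hash of the stage
#' name mixed with the global seed) so that individual stages can be rerun
#' in isolation and still reproduce an end-to-end run.
#'
#' @param global_seed Integer global seed.
#' @param stage Stage name (e.g. `"generate"`, `"split"`, `"search"`).
#' @return A positive integer seed below 2^31.
#' @export
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 10007 + h * 97) %% 2147483629 + 1)
}

#' Configuration of an end-to-end experiment run
#'
#' @param n Number of synthetic samples to generate.
#' @param feature_set `"fused"`, `"all-svi"`, `"all-cvi"`, or the name of a
#'   single registered index (spectral or colour).
#' @param generator A [generator_config()]; its seed is replaced by a
#'   stage seed derived from `seed`.
#' @param search A [search_config()]; likewise reseeded.
#' @param baselines Character vector of baseline families to fit alongside
#'   the search winner (subset of `"plsr"`, `"svm"`, `"bpnn"`, `"rf"`).
#' @param train_fraction Training proportion of the outer split.
#' @param use_preprocessed Logical; compute spectral indices from smoothed +
#'   SNV-transformed spectra instead of raw reflectance (default raw).
#' @param out_dir Optional output directory for written artifacts.
#' @param seed Global integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n = 600L,
                       feature_set = "fused",
                       generator = generator_config(),
                       search = search_config(),
                       baselines = c("plsr", "svm", "bpnn", "rf"),
                       train_fraction = 0.7,
                       use_preprocessed = FALSE,
                       out_dir = NULL,
                       seed = 1L) {
  known <- c("fused", "all-svi", "all-cvi", svi_names(), cvi_names())
  if (!feature_set %in% known) {
    stop(sprintf("unknown feature_set '%s'", feature_set), call. = FALSE)
  }
  structure(list(n = as.integer(n), feature_set = feature_set,
                 generator = generator, search = search,
                 baselines = baselines, train_fraction = train_fraction,
                 use_preprocessed = isTRUE(use_preprocessed),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

pipeline_log <- function(con, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(fmt, ...))
  if (!is.null(con)) cat(line, "\n", file = con, append = TRUE, sep = "")
  invisible(line)
}

#' Run an end-to-end chlorophyll-estimation experiment
#'
#' Executes the full stage order on synthetic data: generate leaf samples,
#' optionally preprocess spectra, compute the requested vegetation-index
#' feature set, split 70/30, run the random model search on the training
#' partition, refit the best candidate on the full training partition,
#' evaluate on the held-out partition, fit any requested baselines, and
#' (when `out_dir` is set) write the feature table, split ids, ranked
#' search results, report table and a timestamped log. Reruns with an
#' identical configuration are reproducible.
#'
#' @param config A [run_config()].
#' @return List with `reports` (list of [model_report()]: the search winner
#'   under family `"automl"`, then baselines), `report_table`
#'   ([experiment_report()] layout), `best_spec`, `search`
#'   ([random_search()] results), `split`, and `features` (the
#'   `feature_table`).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_con <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    log_con <- file.path(config$out_dir, "run.log")
    pipeline_log(log_con, "run start: feature_set=%s n=%d seed=%d",
                 config$feature_set, config$n, config$seed)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      pipeline_log(log_con, "FAILED at stage '%s': %s (partial artifacts above)",
                   stage, conditionMessage(e))
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  gen_cfg <- config$generator
  gen_cfg$seed <- stage_seed(config$seed, "generate")
  ds <- run_stage("generate", generate_dataset(config$n, gen_cfg))
  pipeline_log(log_con, "generated %d samples (generator seed %d)",
               config$n, gen_cfg$seed)

  if (config$use_preprocessed) {
    sd_pre <- run_stage("preprocess", preprocess_dataset(as_spectral_dataset(ds)))
    ds$reflectance <- sd_pre$reflectance
    ds$preprocessed <- TRUE
  }

  ft <- run_stage("features", switch(config$feature_set,
    "fused"   = build_feature_table(ds, "fused"),
    "all-svi" = build_feature_table(ds, "svi"),
    "all-cvi" = build_feature_table(ds, "cvi"),
    build_feature_table(ds, index_names = config$feature_set)))
  pipeline_log(log_con, "feature table: %d rows x %d features (%d dropped)",
               nrow(ft), length(attr(ft, "feature_names")),
               attr(ft, "n_dropped"))

  split <- run_stage("split",
    train_test_split(nrow(ft), config$train_fraction,
                     seed = stage_seed(config$seed, "split")))
  train_ft <- ft[split$train, , drop = FALSE]
  test_ft <- ft[split$test, , drop = FALSE]
  for (x in c("feature_names")) {
    attr(train_ft, x) <- attr(ft, x); attr(test_ft, x) <- attr(ft, x)
  }
  class(train_ft) <- class(test_ft) <- class(ft)

  scfg <- config$search
  scfg$seed <- stage_seed(config$seed, "search")
  search <- run_stage("search", random_search(train_ft, scfg))
  best_spec <- search$specs[[1]]
  pipeline_log(log_con, "search done: best family %s (cv_mse %.4g)",
               best_spec$family, search$ranking$cv_mse[1])

  y_train <- feature_response(train_ft)
  y_test <- feature_response(test_ft)
  evaluate_spec <- function(spec, label) {
    fit <- fit_pipeline(spec, train_ft)
    model_report(config$feature_set, label,
                 y_train, predict(fit, train_ft),
                 y_test, predict(fit, test_ft))
  }
  reports <- list(run_stage("evaluate", evaluate_spec(best_spec, "automl")))
  for (fam in config$baselines) {
    spec <- model_spec(fam, seed = stage_seed(config$seed, paste0("baseline-", fam)))
    reports <- c(reports, list(run_stage(paste0("baseline-", fam),
                                         evaluate_spec(spec, fam))))
    pipeline_log(log_con, "baseline %s: Rp2=%.3f", fam,
                 reports[[length(reports)]]$Rp2)
  }
  report_table <- experiment_report(reports)

  if (!is.null(config$out_dir)) {
    run_stage("write", {
      write_feature_table(ft, file.path(config$out_dir, "features.csv"))
      utils::write.csv(data.frame(sample_id = ft$sample_id,
                                  partition = ifelse(seq_len(nrow(ft)) %in% split$train,
                                                     "train", "test")),
                       file.path(config$out_dir, "split.csv"), row.names = FALSE)
      write_search_results(search, file.path(config$out_dir, "search.csv"))
      write_experiment_report(report_table, file.path(config$out_dir, "report.csv"))
    })
    pipeline_log(log_con, "run complete: automl Rp2=%.3f RMSEp=%.2f",
                 reports[[1]]$Rp2, reports[[1]]$RMSEp)
  }
  list(reports = reports, report_table = report_table, best_spec = best_spec,
       search = search, split = split, features = ft)
}
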