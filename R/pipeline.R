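# End-to-end orchestration: simulate -> preprocess -> extract -> tune ->
# select -> evaluate, with every stage's output persisted to a run directory
# and a manifest of seeds and artifact checksums. Reruns with the same
# config and seed reproduce identical manifest checksums.

#' Pipeline configuration
#'
#' Gathers every tunable of the pipeline with documented defaults. Defaults
#' not fixed by the study design (marked *gap*) are package choices and are
#' listed in the methods vignette.
#'
#' @param class_totals Named recording counts per class; the default scales
#'   the study's 5991:1630:729 imbalance down to 600/160/72.
#' @param filter_kernel Moving-median kernel (odd; *gap*, default 5).
#' @param stride Training-window stride in samples (*gap*, default 40,
#'   non-overlapping).
#' @param test_fraction Held-out fraction for tuning/selection (*gap*, 0.2).
#' @param augment_level Augmentation intensity 1..4 (*gap*, 1), or `NULL`.
#' @param selection_mode `"significant"` or `"nonnegative"` SHAP rule.
#' @param alpha Significance level before Bonferroni correction (0.05).
#' @param pfi_repeats Permutation repeats (*gap*, default 5 in the demo
#'   pipeline for runtime; 10 elsewhere).
#' @param backend Boosting backend (only `"xgb"` fittable here).
#' @param n_trials Bayesian-optimization budget (*gap*, default 25).
#' @param use_preset If `TRUE`, skip tuning and use [paper_optimum()].
#' @param tuning_max_rows Stratified row cap for tuning trials (*gap*, 1500).
#' @param k_folds Stratified CV folds (5).
#' @param vote Consecutive-window trigger rule for detection replay
#'   (*gap*, 1).
#' @param replay_per_class Fall recordings replayed per class for the
#'   lead-time summary (*gap*, 20).
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @param persist_recordings If `TRUE`, write every simulated recording as
#'   CSV under the run directory (slower; default `FALSE` writes a summary
#'   table instead).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(class_totals = c(NON_FALL = 600, SLF = 160, FFH = 72),
                            filter_kernel = 5L, stride = 40L,
                            test_fraction = 0.2, augment_level = 1L,
                            selection_mode = "significant", alpha = 0.05,
                            pfi_repeats = 5L, backend = "xgb",
                            n_trials = 25L, use_preset = FALSE,
                            tuning_max_rows = 1500L, k_folds = 5L,
                            vote = 1L, replay_per_class = 20L, seed = 1L,
                            persist_recordings = FALSE) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    fs_validation_error("test_fraction must be strictly between 0 and 1")
  }
  if (!is.null(augment_level) && !augment_level %in% 1:4) {
    fs_validation_error("augment_level must be in 1..4 or NULL")
  }
  if (filter_kernel %% 2 == 0) fs_validation_error("filter_kernel must be odd")
  if (!selection_mode %in% c("significant", "nonnegative")) {
    fs_validation_error("selection_mode must be 'significant' or 'nonnegative'")
  }
  if (!backend %in% c("xgb", "lgbm", "cat")) {
    fs_validation_error("backend must be one of xgb/lgbm/cat")
  }
  if (n_trials < 1 || k_folds < 2 || vote < 1) {
    fs_validation_error("n_trials >= 1, k_folds >= 2 and vote >= 1 are required")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write/read a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `read_pipeline_config()` returns the validated config; round-trips
#'   losslessly.
#' @export
write_pipeline_config <- function(config, path) {
  vals <- unclass(config)
  vals$class_totals <- as.list(vals$class_totals)  # keep names in YAML map form
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$class_totals)) vals$class_totals <- unlist(vals$class_totals)
  do.call(pipeline_config, vals)
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[fallsense %s] %s", format(Sys.time(), "%H:%M:%S"),
                              sprintf(fmt, ...)))
}

#' Run the full detection pipeline
#'
#' Executes simulation, windowing, feature extraction, hyperparameter
#' tuning (or preset), ensemble feature selection, stratified k-fold
#' cross-validated evaluation, lead-time replay and latency measurement.
#' Every stage's artifact is written under `out_dir`; `manifest.json`
#' records seeds, row counts and MD5 checksums of the deterministic
#' artifacts (latency, being wall-clock, is kept out of the manifest).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if missing).
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with the report, selection, best parameters
#'   and manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  art <- character()  # deterministic artifacts for the manifest

  # -- simulate ------------------------------------------------------------
  spec <- generator_spec(class_totals = config$class_totals,
                         seed = derive_seed(seed, 1))
  recs <- generate_dataset(spec)
  log_stage(quiet, "simulate: %d recordings (%s)", length(recs),
            paste(sprintf("%s=%d", names(config$class_totals), config$class_totals),
                  collapse = ", "))
  summary_df <- do.call(rbind, lapply(recs, function(r) {
    data.frame(recording_id = r$recording_id, klass = r$annotation$klass,
               subtype = r$annotation$subtype, n_samples = nrow(r$samples),
               loss_of_balance_t = r$annotation$loss_of_balance_t,
               impact_t = r$annotation$impact_t)
  }))
  utils::write.csv(summary_df, file.path(out_dir, "recordings.csv"), row.names = FALSE)
  art <- c(art, "recordings.csv")
  if (isTRUE(config$persist_recordings)) {
    rec_dir <- file.path(out_dir, "recordings")
    dir.create(rec_dir, showWarnings = FALSE)
    for (r in recs) write_recording(r, file.path(rec_dir, paste0(r$recording_id, ".csv")))
  }

  # -- preprocess + extract ------------------------------------------------
  windows <- windows_from_recordings(recs, stride = config$stride,
                                     filter_kernel = config$filter_kernel)
  fm <- build_feature_matrix(windows)
  log_stage(quiet, "preprocess: %d labeled windows (%s)", length(windows),
            paste(sprintf("%s=%d", names(fm$n_c), fm$n_c), collapse = ", "))
  feat_df <- data.frame(fm$x, check.names = FALSE)
  feat_df$label <- as.character(fm$labels)
  feat_df$source_id <- fm$source_ids
  utils::write.csv(feat_df, file.path(out_dir, "features.csv"), row.names = FALSE)
  art <- c(art, "features.csv")

  # -- split + tune --------------------------------------------------------
  split <- stratified_split(windows, config$test_fraction,
                            seed = derive_seed(seed, 2))
  train_fm <- build_feature_matrix(split$train)
  if (isTRUE(config$use_preset)) {
    best <- list(best_params = paper_optimum(config$backend), best_score = NA_real_,
                 trials = NULL)
  } else {
    best <- bayes_optimize(train_fm, search_space(config$backend),
                           n_trials = config$n_trials,
                           seed = derive_seed(seed, 3),
                           max_rows = config$tuning_max_rows)
  }
  log_stage(quiet, "tune: best inner macro-F1 %.3f over %d trials",
            best$best_score, config$n_trials)
  jsonlite::write_json(best$best_params, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  art <- c(art, "params.json")

  # -- select --------------------------------------------------------------
  inner <- stratified_split_fm(train_fm, 0.2, seed = derive_seed(seed, 4))
  baseline <- fit_booster(inner$train, params = best$best_params,
                          backend = config$backend, seed = derive_seed(seed, 5))
  shap_res <- shap_select(baseline, inner$test, mode = config$selection_mode,
                          alpha = config$alpha)
  pfi_res <- permutation_importance(baseline, inner$test,
                                    repeats = config$pfi_repeats,
                                    seed = derive_seed(seed, 6))
  sel <- ensemble_select(shap_res, pfi_res)
  log_stage(quiet, "select: SHAP %d + PFI %d -> ensemble %d features",
            length(sel$shap_selected), length(sel$pfi_selected),
            length(sel$ensemble))
  jsonlite::write_json(list(shap_selected = sel$shap_selected,
                            pfi_selected = sel$pfi_selected,
                            ensemble = sel$ensemble,
                            shap_table = shap_res$table,
                            pfi_table = pfi_res$table),
                       file.path(out_dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA)
  art <- c(art, "selection.json")

  # -- evaluate: stratified k-fold CV --------------------------------------
  report <- cross_validate(windows, k = config$k_folds,
                           params = best$best_params, features = sel$ensemble,
                           augment_level = config$augment_level,
                           seed = derive_seed(seed, 7))
  log_stage(quiet, "evaluate: mean macro-F1 %.3f",
            report$aggregate$mean[report$aggregate$metric == "f1"])

  # -- lead-time replay on fresh fall recordings ---------------------------
  final_train <- if (!is.null(config$augment_level)) {
    augment_windows(split$train, level = config$augment_level,
                    seed = derive_seed(seed, 8))
  } else split$train
  final_model <- fit_booster(build_feature_matrix(final_train),
                             params = best$best_params,
                             features = sel$ensemble,
                             seed = derive_seed(seed, 9))
  replay_spec <- generator_spec(
    class_totals = c(NON_FALL = 0, SLF = config$replay_per_class,
                     FFH = config$replay_per_class),
    seed = derive_seed(seed, 10))
  replay_recs <- generate_dataset(replay_spec)
  leads <- lead_time_summary(final_model, replay_recs,
                             features = sel$ensemble, vote = config$vote)
  log_stage(quiet, "lead time: SLF %.0f ms, FFH %.0f ms",
            leads$mean_lead_ms[leads$klass == "SLF"],
            leads$mean_lead_ms[leads$klass == "FFH"])

  test_fm <- build_feature_matrix(split$test)
  latency <- measure_latency(final_model, fm_subset(test_fm, features = final_model$features))

  report_out <- list(folds = report$folds, aggregate = report$aggregate,
                     lead_time = leads,
                     n_windows = length(windows),
                     n_selected = length(sel$ensemble),
                     seed = seed)
  jsonlite::write_json(report_out, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  art <- c(art, "report.json")
  jsonlite::write_json(latency, file.path(out_dir, "latency.json"),
                       auto_unbox = TRUE, digits = NA)

  checksums <- as.list(tools::md5sum(file.path(out_dir, art)))
  names(checksums) <- art
  manifest <- list(package_version = as.character(utils::packageVersion("fallsense")),
                   seed = seed,
                   config = unclass(config)[setdiff(names(config), "persist_recordings")],
                   n_recordings = length(recs), n_windows = length(windows),
                   checksums = checksums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(report = report_out, selection = sel,
                 best_params = best$best_params, manifest = manifest,
                 model = final_model, latency = latency))
}
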