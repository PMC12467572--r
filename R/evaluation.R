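# Stratified cross-validation, macro metrics, per-class PR-AUC, lead-time
# replay and ANOVA/Tukey model comparison.
#
# All macro metrics are one-vs-rest per-class quantities averaged with equal
# class weight. Any zero-denominator per-class term contributes 0 to its
# average (degenerate folds are not addressed by the printed formulas; this
# guard is the package's documented convention).

#' One-vs-rest confusion counts
#'
#' @param truth,predicted Equal-length label vectors over
#'   NON_FALL/SLF/FFH.
#' @return A `confusion_counts` object: K x 4 matrix of TP, FP, TN, FN per
#'   class, with attribute `n` (total rows).
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) == 0) fs_validation_error("empty label vectors")
  if (length(truth) != length(predicted)) {
    fs_validation_error("truth and predicted must have equal length")
  }
  truth <- as_class_factor(truth)
  predicted <- as_class_factor(predicted)
  if (anyNA(truth) || anyNA(predicted)) {
    fs_validation_error("labels must be among NON_FALL/SLF/FFH")
  }
  n <- length(truth)
  out <- t(vapply(CLASSES, function(k) {
    tp <- sum(truth == k & predicted == k)
    fp <- sum(truth != k & predicted == k)
    fn <- sum(truth == k & predicted != k)
    tn <- n - tp - fp - fn
    c(TP = tp, FP = fp, TN = tn, FN = fn)
  }, numeric(4)))
  structure(out, n = n, class = c("confusion_counts", class(out)))
}

#' Macro classification metrics
#'
#' Per-class one-vs-rest accuracy, sensitivity, specificity, F1
#' (`2 TP / (2 TP + FP + FN)`) and MCC, each averaged over the K classes
#' with equal weight. A per-class term with zero denominator contributes 0.
#'
#' @param cc A `confusion_counts` object.
#' @return Named numeric vector `accuracy, sensitivity, specificity, f1, mcc`.
#' @export
macro_metrics <- function(cc) {
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  tp <- cc[, "TP"]; fp <- cc[, "FP"]; tn <- cc[, "TN"]; fn <- cc[, "FN"]
  acc <- safe(tp + tn, tp + tn + fp + fn)
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  f1 <- safe(2 * tp, 2 * tp + fp + fn)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- safe(tp * tn - fp * fn, mcc_den)
  c(accuracy = mean(acc), sensitivity = mean(sens), specificity = mean(spec),
    f1 = mean(f1), mcc = mean(mcc))
}

#' Per-class precision-recall AUC (average precision)
#'
#' One-vs-rest average precision: step-function integration of precision
#' over recall with no interpolation (the conservative standard under class
#' imbalance). Ties in scores are broken by original row order, which keeps
#' the value deterministic.
#'
#' @param truth Label vector.
#' @param scores n x K matrix of class scores (rows summing to 1).
#' @return Named numeric vector of length K; a class absent from `truth`
#'   gets `NA` (reported as missing, not 0).
#' @export
pr_auc_per_class <- function(truth, scores) {
  truth <- as_class_factor(truth)
  stopifnot(nrow(scores) == length(truth))
  vapply(seq_along(CLASSES), function(k) {
    pos <- truth == CLASSES[k]
    if (!any(pos)) return(NA_real_)
    ord <- order(scores[, k], decreasing = TRUE)
    hit <- pos[ord]
    prec_at <- cumsum(hit) / seq_along(hit)
    mean(prec_at[hit])        # average precision over the positives
  }, numeric(1)) |> stats::setNames(CLASSES)
}

#' Lead time from detection to impact
#'
#' `(impact_t - detection_end_time) * 1000` milliseconds. The detection
#' convention is the end time (last sample) of the first fall-predicted
#' window in a stride-1 replay.
#'
#' @param detection_end_time Detection activation time (s).
#' @param impact_t Impact onset (s); must be after the detection.
#' @return Lead time in ms.
#' @export
lead_time <- function(detection_end_time, impact_t) {
  if (any(detection_end_time >= impact_t)) {
    fs_validation_error("detection at/after impact is a missed detection, not a lead time")
  }
  (impact_t - detection_end_time) * 1000
}

#' Replay online detection over one recording
#'
#' Slides stride-1 windows over the active segment, predicts each, and fires
#' on the first run of `vote` consecutive fall-labeled predictions. For a
#' fall recording, a detection whose window ends before `impact_t` yields a
#' lead time; detection at/after impact (or never) is a missed detection.
#'
#' @param model A `fall_model`.
#' @param rec An `imu_recording`.
#' @param features Optional selected-feature subset used by the model.
#' @param vote Consecutive fall windows required to fire (default 1).
#' @param filter_kernel Median-filter kernel for the replay windows.
#' @return List: `fired`, `detection_time` (s), `predicted_class`,
#'   `lead_ms` (NA for non-falls and misses), `missed` (fall recordings
#'   only), `n_windows`.
#' @export
replay_detection <- function(model, rec, features = NULL, vote = 1L,
                             filter_kernel = 5L) {
  wins <- segment_windows(rec, stride = 1L, filter_kernel = filter_kernel)
  if (length(wins) == 0) {
    return(list(fired = FALSE, detection_time = NA_real_,
                predicted_class = NA_character_, lead_ms = NA_real_,
                missed = rec$annotation$klass != "NON_FALL", n_windows = 0L))
  }
  arr <- array(NA_real_, c(WINDOW_LEN, 6L, length(wins)))
  for (i in seq_along(wins)) arr[, , i] <- window_matrix(wins[[i]])
  x <- features_from_array(arr)
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  pred <- predict(model, x)$labels
  is_fall <- pred %in% c("SLF", "FFH")
  fired_at <- NA_integer_
  run <- 0L
  for (i in seq_along(is_fall)) {
    run <- if (is_fall[i]) run + 1L else 0L
    if (run >= vote) { fired_at <- i; break }
  }
  ann <- rec$annotation
  is_fall_rec <- ann$klass != "NON_FALL"
  if (is.na(fired_at)) {
    return(list(fired = FALSE, detection_time = NA_real_,
                predicted_class = NA_character_, lead_ms = NA_real_,
                missed = is_fall_rec, n_windows = length(wins)))
  }
  det_t <- wins[[fired_at]]$end_time
  lead <- NA_real_
  missed <- FALSE
  if (is_fall_rec) {
    if (det_t < ann$impact_t - TIME_TOL_S) lead <- (ann$impact_t - det_t) * 1000
    else missed <- TRUE
  }
  list(fired = TRUE, detection_time = det_t,
       predicted_class = as.character(pred[fired_at]),
       lead_ms = lead, missed = missed, n_windows = length(wins))
}

#' Summarize lead times over a set of recordings
#'
#' Replays every fall recording and aggregates first-detection lead times
#' per fall class; missed detections are counted separately and excluded
#' from the means.
#'
#' @param model A `fall_model`.
#' @param recordings List of `imu_recording`.
#' @inheritParams replay_detection
#' @return Data frame per fall class: n, detected, missed, mean/sd lead (ms).
#' @export
lead_time_summary <- function(model, recordings, features = NULL, vote = 1L) {
  rows <- lapply(c("SLF", "FFH"), function(kl) {
    recs <- Filter(function(r) r$annotation$klass == kl, recordings)
    if (length(recs) == 0) {
      return(data.frame(klass = kl, n = 0L, detected = 0L, missed = 0L,
                        mean_lead_ms = NA_real_, sd_lead_ms = NA_real_))
    }
    res <- lapply(recs, function(r) replay_detection(model, r, features, vote))
    leads <- vapply(res, function(z) z$lead_ms, 0)
    missed <- vapply(res, function(z) isTRUE(z$missed) || !z$fired, TRUE)
    data.frame(klass = kl, n = length(recs),
               detected = sum(!missed), missed = sum(missed),
               mean_lead_ms = if (any(!is.na(leads))) mean(leads, na.rm = TRUE) else NA_real_,
               sd_lead_ms = if (sum(!is.na(leads)) > 1) stats::sd(leads, na.rm = TRUE) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Stratified k-fold cross-validation of the pipeline
#'
#' Folds are stratified so each retains the global class proportions within
#' one window. Per fold, augmentation (optional) and any feature selection
#' refit happen on the training portion only; the model is fitted with
#' inverse-frequency weights and scored on the held-out fold.
#'
#' @param data Either a list of labeled windows (enables per-fold
#'   augmentation) or a `feature_matrix` (no augmentation possible).
#' @param k Number of folds (default 5); every class count must be >= k.
#' @param params Hyperparameters for [fit_booster()].
#' @param features Optional selected-feature subset.
#' @param augment_level Augmentation intensity 1..4, or `NULL` to skip
#'   (ignored with a matrix input).
#' @param select_per_fold If `TRUE`, runs the full SHAP+PFI ensemble
#'   selection inside each training fold (slower; default `FALSE`, in which
#'   case `features` — typically selected on a prior training split — is
#'   used as-is).
#' @param pfi_repeats Permutation repeats when `select_per_fold = TRUE`.
#' @param seed Integer seed controlling fold assignment, augmentation and
#'   fits.
#' @return An `evaluation_report`: per-fold macro metrics and per-class
#'   PR-AUC, plus aggregate mean and sd.
#' @export
cross_validate <- function(data, k = 5L, params = NULL, features = NULL,
                           augment_level = 1L, select_per_fold = FALSE,
                           pfi_repeats = 5L, seed = 1L) {
  k <- as.integer(k)
  is_windows <- !inherits(data, "feature_matrix")
  labels <- if (is_windows) {
    as_class_factor(vapply(data, function(w) as.character(w$label), ""))
  } else data$labels
  tab <- table(labels)
  if (any(tab < k)) {
    fs_stratification_error(sprintf("every class needs >= %d windows for %d-fold CV", k, k))
  }
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (kl in levels(labels)) {
    idx <- sample(which(labels == kl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fm_all <- if (is_windows) NULL else data
  fold_rows <- list()
  for (f in seq_len(k)) {
    te_idx <- which(fold == f)
    tr_idx <- which(fold != f)
    if (is_windows) {
      tr_windows <- data[tr_idx]
      if (!is.null(augment_level)) {
        tr_windows <- augment_windows(tr_windows, level = augment_level,
                                      seed = derive_seed(seed, f))
      }
      tr_fm <- build_feature_matrix(tr_windows)
      te_fm <- build_feature_matrix(data[te_idx])
    } else {
      tr_fm <- fm_subset(fm_all, rows = tr_idx)
      te_fm <- fm_subset(fm_all, rows = te_idx)
    }
    feats <- features
    if (select_per_fold) {
      inner <- stratified_split_fm(tr_fm, 0.2, seed = derive_seed(seed, 100 + f))
      base <- fit_booster(inner$train, params = params, features = NULL,
                          seed = derive_seed(seed, 200 + f))
      sel <- ensemble_select(
        shap_select(base, inner$test),
        permutation_importance(base, inner$test, repeats = pfi_repeats,
                               seed = derive_seed(seed, 300 + f)),
        registry = colnames(tr_fm$x))
      feats <- sel$ensemble
    }
    model <- fit_booster(tr_fm, params = params, features = feats,
                         seed = derive_seed(seed, 400 + f))
    pred <- predict(model, te_fm)
    mm <- macro_metrics(confusion_counts(te_fm$labels, pred$labels))
    pr <- pr_auc_per_class(te_fm$labels, pred$scores)
    fold_rows[[f]] <- data.frame(fold = f, t(mm),
                                 pr_auc_non_fall = pr[["NON_FALL"]],
                                 pr_auc_slf = pr[["SLF"]],
                                 pr_auc_ffh = pr[["FFH"]])
  }
  folds <- do.call(rbind, fold_rows)
  metric_cols <- setdiff(names(folds), "fold")
  aggregate <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(cn) mean(folds[[cn]]), 0),
    sd = vapply(metric_cols, function(cn) stats::sd(folds[[cn]]), 0))
  structure(list(folds = folds, aggregate = aggregate, k = k, seed = seed),
            class = "evaluation_report")
}

# stratified split of a feature_matrix (rows), largest-remainder per class
stratified_split_fm <- function(fm, test_fraction = 0.2, seed = 1L) {
  set.seed(as.integer(seed))
  tab <- table(fm$labels)
  test_counts <- largest_remainder(as.numeric(tab), test_fraction)
  names(test_counts) <- names(tab)
  te <- integer()
  for (kl in names(tab)) {
    pool <- which(fm$labels == kl)
    te <- c(te, sort(sample(pool, min(test_counts[[kl]], length(pool) - 1L))))
  }
  list(train = fm_subset(fm, rows = setdiff(seq_along(fm$labels), te)),
       test = fm_subset(fm, rows = sort(te)))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d-fold stratified CV\n", x$k))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-16s %.3f +/- %.3f\n", agg$metric[i], agg$mean[i], agg$sd[i]))
  }
  invisible(x)
}

#' Scoring latency per window
#'
#' Wall-clock prediction time divided by window count, warm-up excluded.
#' Hardware-dependent; reported with host metadata, never compared against
#' published figures.
#'
#' @param model A `fall_model`.
#' @param fm A `feature_matrix` with at least 100 rows.
#' @param repeats Timed repetitions after one warm-up pass.
#' @return List: `ms_per_window`, `n_windows`, `host` (R version, platform).
#' @export
measure_latency <- function(model, fm, repeats = 3L) {
  n <- nrow(fm$x)
  if (n < 100) fs_parameter_error("latency measurement needs >= 100 windows")
  invisible(predict(model, fm))  # warm-up
  t0 <- Sys.time()
  for (i in seq_len(repeats)) invisible(predict(model, fm))
  elapsed_ms <- as.numeric(difftime(Sys.time(), t0, units = "secs")) * 1000
  list(ms_per_window = elapsed_ms / (repeats * n), n_windows = n,
       host = list(r_version = R.version.string, platform = R.version$platform))
}

#' Compare models by ANOVA and Tukey HSD on fold-level metrics
#'
#' One-way ANOVA across models on per-fold metric values, followed by Tukey
#' honestly-significant-difference pairwise tests at `alpha`. The grouping
#' string orders models by mean and separates significance tiers, e.g.
#' `"(1),(2) > (3)"`.
#'
#' @param metric_table Data frame with columns `model` and `value` (one row
#'   per model x fold); each model must have the same number of folds.
#' @param alpha Significance level, default 0.05.
#' @return List: `anova` (F, p), `tukey` (pairwise table), `grouping`.
#' @export
compare_models <- function(metric_table, alpha = 0.05) {
  stopifnot(all(c("model", "value") %in% names(metric_table)))
  metric_table$model <- factor(metric_table$model)
  m <- nlevels(metric_table$model)
  if (m < 2) fs_validation_error("at least 2 models are required")
  if (length(unique(table(metric_table$model))) != 1) {
    fs_validation_error("equal fold counts per model are required")
  }
  if (stats::var(metric_table$value) < 1e-24) {
    means <- tapply(metric_table$value, metric_table$model, mean)
    pairs <- t(utils::combn(levels(metric_table$model), 2))
    tukey <- data.frame(pair = paste(pairs[, 1], pairs[, 2], sep = "-"),
                        diff = 0, p_adj = 1, significant = FALSE)
    return(list(anova = c(F = 0, p = 1), tukey = tukey,
                grouping = paste(sprintf("(%s)", names(sort(means, decreasing = TRUE))),
                                 collapse = ","),
                means = means))
  }
  fit <- stats::aov(value ~ model, data = metric_table)
  an <- summary(fit)[[1]]
  Fv <- an[["F value"]][1]
  pv <- an[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$model
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha)
  rownames(tukey) <- NULL
  means <- sort(tapply(metric_table$value, metric_table$model, mean),
                decreasing = TRUE)
  sig_between <- function(a, b) {
    key1 <- paste(a, b, sep = "-"); key2 <- paste(b, a, sep = "-")
    row <- tukey[tukey$pair %in% c(key1, key2), ]
    nrow(row) > 0 && any(row$significant)
  }
  tiers <- list(names(means)[1])
  for (nm in names(means)[-1]) {
    last <- tiers[[length(tiers)]]
    if (all(vapply(last, function(o) !sig_between(o, nm), TRUE))) {
      tiers[[length(tiers)]] <- c(last, nm)
    } else {
      tiers[[length(tiers) + 1L]] <- nm
    }
  }
  grouping <- paste(vapply(tiers, function(tr)
    paste(sprintf("(%s)", tr), collapse = ","), ""), collapse = " > ")
  list(anova = c(F = Fv, p = pv), tukey = tukey, grouping = grouping,
       means = means)
}
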