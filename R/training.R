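# Class-weighted gradient-boosted tree training with Bayesian hyperparameter
# optimization maximizing validation macro-F1.
#
# Sample weights follow the inverse-frequency rule w_i = N / (K * n_c(i)),
# which gives every class the same total weight (sum of w_i is exactly N).

#' Inverse-frequency sample weights
#'
#' `w_i = N / (K * n_c(i))` where `N` is the number of samples, `K` the
#' number of classes and `n_c(i)` the count of sample i's class. Balanced
#' labels give all-ones weights; the weights of any label vector sum to `N`.
#'
#' @param labels Factor (or character) class labels; every level present.
#' @return Numeric weight per sample.
#' @export
compute_sample_weights <- function(labels) {
  if (length(labels) == 0) fs_validation_error("labels must be non-empty")
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  n_c <- table(f)
  K <- nlevels(f)
  N <- length(f)
  as.numeric(N / (K * n_c[f]))
}

#' Hyperparameter search space for a boosting backend
#'
#' The bounds are the published search ranges: learning rate
#' log-uniform in [0.005, 0.30]; boosting iterations in [100, 800]; maximum
#' depth in [3, 10]; row subsample in [0.50, 1.00]; column sample in
#' [0.30, 1.00]; minimum loss reduction in [0, 5]; minimum child weight
#' integer [1, 10] (xgb) or log-uniform [1e-3, 10] (lgbm); leaves [15, 255]
#' (lgbm only); bagging temperature [0, 1] and L2 leaf regularization
#' log-uniform [1e-3, 10] (cat only); L1/L2 coefficients log-uniform
#' [1e-6, 10].
#'
#' @param backend `"xgb"`, `"lgbm"` or `"cat"`.
#' @return Data frame with columns `name`, `scale`
#'   (`"uniform"`/`"log-uniform"`/`"integer-uniform"`), `low`, `high`.
#' @export
search_space <- function(backend = c("xgb", "lgbm", "cat")) {
  backend <- match.arg(backend)
  p <- function(name, scale, low, high) data.frame(name = name, scale = scale,
                                                   low = low, high = high)
  common <- rbind(
    p("learning_rate", "log-uniform", 0.005, 0.30),
    p("n_rounds", "integer-uniform", 100, 800),
    p("max_depth", "integer-uniform", 3, 10))
  sp <- switch(backend,
    xgb = rbind(common,
      p("subsample", "uniform", 0.50, 1.00),
      p("colsample_bytree", "uniform", 0.30, 1.00),
      p("gamma", "uniform", 0, 5),
      p("min_child_weight", "integer-uniform", 1, 10),
      p("reg_alpha", "log-uniform", 1e-6, 10),
      p("reg_lambda", "log-uniform", 1e-6, 10)),
    lgbm = rbind(common,
      p("subsample", "uniform", 0.50, 1.00),
      p("colsample_bytree", "uniform", 0.30, 1.00),
      p("min_split_gain", "uniform", 0, 5),
      p("min_child_weight", "log-uniform", 1e-3, 10),
      p("num_leaves", "integer-uniform", 15, 255),
      p("reg_alpha", "log-uniform", 1e-6, 10),
      p("reg_lambda", "log-uniform", 1e-6, 10)),
    cat = rbind(common,
      p("colsample_bytree", "uniform", 0.30, 1.00),
      p("bagging_temperature", "uniform", 0, 1),
      p("l2_leaf_reg", "log-uniform", 1e-3, 10)))
  attr(sp, "backend") <- backend
  sp
}

#' Published optimum presets per backend
#'
#' The tuned configurations reported for each backend, usable without
#' rerunning the search. They are data-derived values from the original
#' study's dataset, shipped for convenience.
#'
#' @param backend `"xgb"`, `"lgbm"` or `"cat"`.
#' @return Named list of hyperparameters.
#' @export
paper_optimum <- function(backend = c("xgb", "lgbm", "cat")) {
  backend <- match.arg(backend)
  switch(backend,
    xgb = list(learning_rate = 0.298, n_rounds = 254L, max_depth = 9L,
               subsample = 0.959, colsample_bytree = 0.948, gamma = 0.036,
               min_child_weight = 4L, reg_alpha = 0.006, reg_lambda = 1.13e-5),
    lgbm = list(learning_rate = 0.020, n_rounds = 760L, max_depth = 10L,
                subsample = 0.894, colsample_bytree = 0.382,
                min_split_gain = 0.919, min_child_weight = 0.038,
                num_leaves = 203L, reg_alpha = 0.030, reg_lambda = 7.47e-4),
    cat = list(learning_rate = 0.092, n_rounds = 539L, max_depth = 8L,
               colsample_bytree = 0.892, bagging_temperature = 0.657,
               l2_leaf_reg = 1.146))
}

#' Validate hyperparameters against a backend's search space
#'
#' @param params Named list of hyperparameters.
#' @param backend Backend id.
#' @return `params`, invisibly; raises a validation error when any value
#'   falls outside its bound.
#' @export
validate_params <- function(params, backend = "xgb") {
  sp <- search_space(backend)
  for (i in seq_len(nrow(sp))) {
    nm <- sp$name[i]
    if (is.null(params[[nm]])) next
    v <- params[[nm]]
    if (v < sp$low[i] - 1e-12 || v > sp$high[i] + 1e-12) {
      fs_validation_error(sprintf("%s = %g outside search bound [%g, %g]",
                                  nm, v, sp$low[i], sp$high[i]))
    }
  }
  invisible(params)
}

#' Fit a weighted multiclass boosted-tree model
#'
#' Softmax objective over the three classes, fixed iteration count (no early
#' stopping), single-threaded for determinism under `seed`. Only the
#' XGBoost backend is available in this installation; requesting `"lgbm"`
#' or `"cat"` raises an environment error naming the backend, keeping the
#' three-backend contract explicit.
#'
#' @param train A `feature_matrix` (training rows).
#' @param params Hyperparameters (see [search_space()]); defaults to
#'   [paper_optimum()] for the backend.
#' @param backend `"xgb"`, `"lgbm"` or `"cat"`.
#' @param weights Per-row weights; defaults to [compute_sample_weights()]
#'   of the training labels. Pass `rep(1, n)` for unweighted fits.
#' @param features Optional feature-name subset (registry names) to train on.
#' @param seed Integer seed.
#' @return A `fall_model`: the fitted booster plus its feature registry
#'   subset, hyperparameters and training metadata.
#' @export
fit_booster <- function(train, params = NULL, backend = "xgb",
                        weights = NULL, features = NULL, seed = 1L) {
  if (backend != "xgb") {
    fs_environment_error(sprintf(
      "backend '%s' is not installed in this environment; only 'xgb' is available",
      backend))
  }
  if (is.null(params)) params <- paper_optimum(backend)
  validate_params(params, backend)
  fm <- fm_subset(train, features = features)
  if (is.null(weights)) weights <- compute_sample_weights(fm$labels)
  if (length(weights) != nrow(fm$x)) {
    fs_validation_error("weights length must equal the number of training rows")
  }
  y <- as.integer(fm$labels) - 1L
  dtrain <- xgboost::xgb.DMatrix(fm$x, label = y, weight = weights)
  xgb_params <- list(
    objective = "multi:softprob", num_class = length(CLASSES),
    eta = params$learning_rate, max_depth = params$max_depth,
    subsample = params$subsample %||% 1,
    colsample_bytree = params$colsample_bytree %||% 1,
    gamma = params$gamma %||% 0,
    min_child_weight = params$min_child_weight %||% 1,
    alpha = params$reg_alpha %||% 0, lambda = params$reg_lambda %||% 1,
    nthread = 1, seed = as.integer(seed), tree_method = "hist")
  booster <- xgboost::xgb.train(params = xgb_params, data = dtrain,
                                nrounds = params$n_rounds, verbose = 0)
  structure(list(backend = backend, params = params, booster = booster,
                 features = colnames(fm$x), classes = CLASSES,
                 meta = list(seed = as.integer(seed),
                             weight_scheme = if (stats::var(weights) < 1e-12) "uniform"
                                             else "inverse-frequency",
                             n_train = nrow(fm$x))),
            class = "fall_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fall_model <- function(x, ...) {
  cat(sprintf("<fall_model> backend=%s, %d features, %d rounds, trained on %d rows (%s weights)\n",
              x$backend, length(x$features), x$params$n_rounds,
              x$meta$n_train, x$meta$weight_scheme))
  invisible(x)
}

#' Predict classes and per-class scores
#'
#' @param object A `fall_model`.
#' @param newdata A `feature_matrix` or bare numeric matrix with (at least)
#'   the model's feature columns.
#' @param ... Unused.
#' @return List with `labels` (factor) and `scores` (n x 3 matrix of class
#'   probabilities summing to 1 per row). Ties break to the lowest class
#'   index.
#' @export
predict.fall_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else as.matrix(newdata)
  missing <- setdiff(object$features, colnames(x))
  if (length(missing)) {
    fs_registry_error(sprintf("prediction input lacks model feature(s): %s",
                              paste(utils::head(missing, 5), collapse = ", ")))
  }
  x <- x[, object$features, drop = FALSE]
  scores <- predict(object$booster, x)
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = length(object$classes), byrow = TRUE)
  colnames(scores) <- object$classes
  labels <- factor(object$classes[max.col(scores, ties.method = "first")],
                   levels = object$classes)
  list(labels = labels, scores = scores)
}

# ---- Bayesian optimization (sequential model-based search) ----------------

# Map a unit-cube row to a named parameter list per the space definition.
decode_config <- function(u, space) {
  out <- list()
  for (i in seq_len(nrow(space))) {
    lo <- space$low[i]; hi <- space$high[i]
    v <- switch(space$scale[i],
      "uniform" = lo + u[i] * (hi - lo),
      "log-uniform" = exp(log(lo) + u[i] * (log(hi) - log(lo))),
      "integer-uniform" = as.integer(round(lo + u[i] * (hi - lo))))
    out[[space$name[i]]] <- v
  }
  out
}

# Squared Euclidean cross-distance between row sets.
sqdist <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
}

#' Bayesian hyperparameter optimization maximizing validation macro-F1
#'
#' Sequential model-based search: a Latin-hypercube initial design followed
#' by a Gaussian-process surrogate (RBF kernel) with expected-improvement
#' proposals over a random candidate pool. Each trial fits a weighted
#' booster on an inner stratified training part and scores macro-F1 on the
#' inner validation part. Deterministic under `seed`.
#'
#' @param train A `feature_matrix`.
#' @param space Search space from [search_space()]; only `"xgb"` is
#'   fittable in this installation.
#' @param n_trials Number of trials (>= 1); default 50.
#' @param inner_fraction Inner validation fraction (stratified); default 0.2.
#' @param seed Integer seed.
#' @param max_rows Optional cap: trials are evaluated on a stratified
#'   subsample of at most this many rows (tuning-time control); `Inf` keeps
#'   all rows.
#' @return List with `best_params`, `best_score` and the full `trials` log.
#' @export
bayes_optimize <- function(train, space = search_space("xgb"), n_trials = 50L,
                           inner_fraction = 0.2, seed = 1L, max_rows = Inf) {
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) fs_parameter_error("n_trials must be >= 1")
  backend <- attr(space, "backend") %||% "xgb"
  set.seed(as.integer(seed))
  fm <- train
  if (is.finite(max_rows) && nrow(fm$x) > max_rows) {
    keep <- integer()
    frac <- max_rows / nrow(fm$x)
    for (kl in levels(fm$labels)) {
      pool <- which(fm$labels == kl)
      keep <- c(keep, sort(sample(pool, max(2L, round(length(pool) * frac)))))
    }
    fm <- fm_subset(fm, rows = sort(keep))
  }
  # inner stratified split
  idx_val <- integer()
  for (kl in levels(fm$labels)) {
    pool <- which(fm$labels == kl)
    if (length(pool) < 2) fs_stratification_error("each class needs >= 2 rows for the inner split")
    idx_val <- c(idx_val, sort(sample(pool, max(1L, round(length(pool) * inner_fraction)))))
  }
  idx_tr <- setdiff(seq_along(fm$labels), idx_val)
  inner_tr <- fm_subset(fm, rows = idx_tr)
  inner_val <- fm_subset(fm, rows = sort(idx_val))
  if (nlevels(droplevels(inner_tr$labels)) < 2 ||
      nlevels(droplevels(inner_val$labels)) < 2) {
    fs_stratification_error("degenerate single-class inner split")
  }
  d <- nrow(space)
  objective <- function(u) {
    cfg <- decode_config(u, space)
    model <- fit_booster(inner_tr, params = cfg, backend = backend, seed = seed)
    pred <- predict(model, inner_val)
    macro_metrics(confusion_counts(inner_val$labels, pred$labels))[["f1"]]
  }
  n_init <- min(n_trials, max(4L, min(8L, n_trials)))
  U <- lhs::randomLHS(n_init, d)
  y <- apply(U, 1, objective)
  trials <- data.frame(trial = seq_len(n_init), score = y)
  while (nrow(U) < n_trials) {
    # GP surrogate on normalized scores, EI over random candidates
    ls <- 0.3 * sqrt(d)
    K <- exp(-sqdist(U, U) / (2 * ls^2)) + diag(1e-4, nrow(U))
    ym <- mean(y); ys <- stats::sd(y); if (!is.finite(ys) || ys < 1e-9) ys <- 1
    yn <- (y - ym) / ys
    Kc <- chol(K)
    alpha <- backsolve(Kc, forwardsolve(t(Kc), yn))
    cand <- matrix(stats::runif(500 * d), 500, d)
    Ks <- exp(-sqdist(cand, U) / (2 * ls^2))
    mu <- as.vector(Ks %*% alpha)
    V <- forwardsolve(t(Kc), t(Ks))
    s2 <- pmax(1 - colSums(V^2), 1e-12)
    s <- sqrt(s2)
    best <- max(yn)
    z <- (mu - best) / s
    ei <- s * (z * stats::pnorm(z) + stats::dnorm(z))
    u_new <- cand[which.max(ei), ]
    U <- rbind(U, u_new)
    y <- c(y, objective(u_new))
    trials <- rbind(trials, data.frame(trial = nrow(U), score = y[length(y)]))
  }
  best_i <- which.max(y)
  cfgs <- lapply(seq_len(nrow(U)), function(i) decode_config(U[i, ], space))
  trials$params <- I(cfgs)
  list(best_params = cfgs[[best_i]], best_score = y[best_i], trials = trials,
       backend = backend)
}
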