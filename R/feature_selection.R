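# Ensemble feature selection: SHAP-based statistical inference combined with
# permutation feature importance, the definitive set being their union.
#
# SHAP-Select regression design: with K classes and per-observation,
# per-class SHAP contributions phi_ijk (computed exactly from the tree
# structure), the linear predictor of observation i toward class k is
#   eta_ik = bias_ik + sum_j beta_j * phi_ijk
# with a softmax likelihood over k. One shared coefficient per feature (J
# coefficients in total; the model's own bias contribution enters as a fixed
# offset, so beta = 1 recovers the booster's margins). Wald p-values come
# from the penalized observed information matrix; the Bonferroni divisor is
# J, since one coefficient per feature is tested.

#' Per-class SHAP contributions from a fitted booster
#'
#' Exact tree-path SHAP values (no sampling), one J-vector per observation
#' and class, plus the per-class bias terms.
#'
#' @param model A `fall_model`.
#' @param fm A `feature_matrix` (or matrix with the model's features).
#' @return List with `phi` (n x K x J array) and `bias` (n x K matrix).
#' @export
shap_contributions <- function(model, fm) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  x <- x[, model$features, drop = FALSE]
  contrib <- predict(model$booster, x, predcontrib = TRUE)
  J <- length(model$features)
  stopifnot(length(dim(contrib)) == 3, dim(contrib)[3] == J + 1)
  list(phi = contrib[, , seq_len(J), drop = FALSE],
       bias = contrib[, , J + 1])
}

# Penalized shared-coefficient multinomial fit of labels on SHAP values.
# Returns beta, se, p, convergence flag.
shap_regression <- function(phi, bias, y, ridge = 1e-6) {
  n <- dim(phi)[1]; K <- dim(phi)[2]; J <- dim(phi)[3]
  Y <- diag(K)[as.integer(y), , drop = FALSE]   # n x K one-hot
  eta_p <- function(beta) {
    eta <- bias
    for (k in seq_len(K)) eta[, k] <- eta[, k] + phi[, k, ] %*% beta
    eta <- eta - apply(eta, 1, max)
    p <- exp(eta)
    p / rowSums(p)
  }
  nll <- function(beta) {
    p <- eta_p(beta)
    -sum(log(pmax(rowSums(Y * p), 1e-300))) + 0.5 * ridge * sum(beta^2)
  }
  grad <- function(beta) {
    p <- eta_p(beta)
    r <- p - Y                                   # n x K
    g <- numeric(J)
    for (k in seq_len(K)) g <- g + crossprod(phi[, k, ], r[, k])
    as.numeric(g) + ridge * beta
  }
  fit <- stats::optim(rep(1, J), nll, grad, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-10))
  converged <- fit$convergence == 0
  # Quasi-complete separation drives the MLE to infinity and the observed
  # information to singularity (Wald SEs explode). Detect it through a
  # saturated mean deviance and refit with a stronger, stabilizing ridge.
  mean_nll <- (fit$value - 0.5 * ridge * sum(fit$par^2)) / n
  saturated <- mean_nll < 0.02
  if (!converged || saturated) {
    # Prior weight comparable to the data keeps the fit off the boundary;
    # scaling with n keeps the penalized deviance informative at any size.
    ridge <- 0.05 * n
    fit <- stats::optim(rep(1, J), nll, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-10))
  }
  beta <- fit$par
  # observed information: H = sum_i Phi_i diag(p_i) Phi_i' - (Phi_i p_i)(...)'
  p <- eta_p(beta)
  H <- diag(ridge, J)
  for (i in seq_len(n)) {
    Phi <- matrix(phi[i, , ], nrow = K)          # K x J
    wp <- p[i, ]
    Pw <- Phi * wp
    H <- H + crossprod(Pw, Phi) - tcrossprod(colSums(Pw))
  }
  H <- (H + t(H)) / 2
  cov <- tryCatch(solve(H), error = function(e) {
    solve(H + diag(1e-6 * max(diag(H)), J))
  })
  se <- sqrt(pmax(diag(cov), 0))
  z <- ifelse(se > 0, beta / se, 0)
  pval <- 2 * stats::pnorm(-abs(z))
  pval[se == 0] <- 1
  list(beta = beta, se = se, p = pval, converged = converged,
       saturated = saturated, ridge = ridge)
}

#' SHAP-Select feature selection
#'
#' Regresses the true class labels on the per-feature SHAP contributions of
#' a fitted booster (shared coefficient across class logits, softmax
#' likelihood), then keeps features by coefficient sign and Wald
#' significance after Bonferroni correction (`alpha / J`).
#' `mode = "significant"` keeps features with a significantly positive
#' coefficient; `mode = "nonnegative"` keeps every feature that is not
#' significantly negative.
#'
#' @param model A `fall_model` fitted on the same feature registry.
#' @param val Validation `feature_matrix` with at least two classes present.
#' @param mode `"significant"` (default) or `"nonnegative"`.
#' @param alpha Family-wise significance level before Bonferroni division;
#'   default 0.05.
#' @return List with `selected` (feature names), `table` (per-feature beta,
#'   SE, p-value and decision among significant_positive / nonsignificant /
#'   significant_negative), `mode`, `alpha`, `threshold` and `diagnostics`.
#' @export
shap_select <- function(model, val, mode = c("significant", "nonnegative"),
                        alpha = 0.05) {
  mode <- match.arg(mode)
  if (nlevels(droplevels(val$labels)) < 2) {
    fs_validation_error("validation set is single-class; SHAP regression is undefined")
  }
  sc <- shap_contributions(model, val)
  reg <- shap_regression(sc$phi, sc$bias, val$labels)
  J <- length(model$features)
  threshold <- alpha / J
  decision <- ifelse(reg$p < threshold,
                     ifelse(reg$beta > 0, "significant_positive", "significant_negative"),
                     "nonsignificant")
  tab <- data.frame(feature = model$features, beta = reg$beta, se = reg$se,
                    p = reg$p, decision = decision, stringsAsFactors = FALSE)
  selected <- switch(mode,
    significant = tab$feature[tab$decision == "significant_positive"],
    nonnegative = tab$feature[tab$decision != "significant_negative"])
  list(selected = selected, table = tab, mode = mode, alpha = alpha,
       threshold = threshold,
       diagnostics = list(converged = reg$converged,
                          saturated = reg$saturated,
                          ridge = reg$ridge,
                          ridge_fallback = reg$ridge > 1e-6))
}

#' Permutation feature importance
#'
#' Baseline macro-F1 on the validation set, then for each feature `R`
#' independent within-column permutations; the importance is the mean drop
#' `baseline - permuted macro-F1`. A feature is retained iff its mean drop
#' is strictly positive. Permuting a constant column leaves predictions
#' unchanged, so its drop is exactly 0. Deterministic under `seed`.
#'
#' @param model A `fall_model`.
#' @param val Validation `feature_matrix`.
#' @param repeats Number of permutations per feature (default 10).
#' @param seed Integer seed.
#' @return List with `baseline`, `table` (feature, mean_drop, retained),
#'   `drops` (J x R matrix of per-repeat drops) and `retained` names.
#' @export
permutation_importance <- function(model, val, repeats = 10L, seed = 1L) {
  repeats <- as.integer(repeats)
  if (repeats < 1L) fs_parameter_error("repeats must be >= 1")
  set.seed(as.integer(seed))
  x <- val$x[, model$features, drop = FALSE]
  truth <- val$labels
  baseline <- macro_metrics(confusion_counts(truth, predict(model, x)$labels))[["f1"]]
  J <- ncol(x)
  n <- nrow(x)
  drops <- matrix(NA_real_, J, repeats,
                  dimnames = list(colnames(x), NULL))
  for (j in seq_len(J)) {
    orig <- x[, j]
    for (r in seq_len(repeats)) {
      perm <- sample.int(n)
      if (max(abs(orig[perm] - orig)) == 0) {   # constant column: identity
        drops[j, r] <- 0
        next
      }
      x[, j] <- orig[perm]
      f1 <- macro_metrics(confusion_counts(truth, predict(model, x)$labels))[["f1"]]
      drops[j, r] <- baseline - f1
    }
    x[, j] <- orig
  }
  mean_drop <- rowMeans(drops)
  tab <- data.frame(feature = colnames(x), mean_drop = mean_drop,
                    retained = mean_drop > 0, stringsAsFactors = FALSE)
  list(baseline = baseline, table = tab, drops = drops,
       retained = tab$feature[tab$retained])
}

#' Ensemble selection: union of SHAP-Select and PFI features
#'
#' @param shap_set SHAP-Select result (from [shap_select()]) or a character
#'   vector of feature names.
#' @param pfi_set PFI result (from [permutation_importance()]) or character
#'   vector.
#' @param registry Feature registry the sets must come from; defaults to
#'   the canonical 168-name registry.
#' @return A `selection_result`: `shap_selected`, `pfi_selected`, `ensemble`
#'   (exact union, in stable registry order) and `diagnostics` holding the
#'   two input tables when available.
#' @export
ensemble_select <- function(shap_set, pfi_set, registry = feature_registry()) {
  get_set <- function(s, field) if (is.character(s)) s else s[[field]]
  shap_names <- get_set(shap_set, "selected")
  pfi_names <- get_set(pfi_set, "retained")
  unknown <- setdiff(c(shap_names, pfi_names), registry)
  if (length(unknown)) {
    fs_registry_error(sprintf("feature name(s) not in registry: %s",
                              paste(utils::head(unknown, 5), collapse = ", ")))
  }
  ensemble <- registry[registry %in% union(shap_names, pfi_names)]
  structure(list(
    shap_selected = registry[registry %in% shap_names],
    pfi_selected = registry[registry %in% pfi_names],
    ensemble = ensemble,
    diagnostics = list(
      shap = if (!is.character(shap_set)) shap_set$table else NULL,
      pfi = if (!is.character(pfi_set)) pfi_set$table else NULL)),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> SHAP %d + PFI %d -> ensemble %d features\n",
              length(x$shap_selected), length(x$pfi_selected), length(x$ensemble)))
  invisible(x)
}
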