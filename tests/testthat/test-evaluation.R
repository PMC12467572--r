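test_that("confusion counts tally one-vs-rest cells", {
  truth <- rep(c("NON_FALL", "SLF", "FFH"), times = c(10, 5, 5))
  cc <- confusion_counts(truth, truth)
  expect_equal(unname(cc[, "TP"]), c(10, 5, 5))
  expect_equal(sum(cc[, "FP"]), 0)
  expect_equal(sum(cc[, "FN"]), 0)
  all_nf <- rep("NON_FALL", 20)
  cc2 <- confusion_counts(truth, all_nf)
  expect_equal(cc2["SLF", "FN"], 5)
  expect_equal(cc2["NON_FALL", "FP"], 10)
  expect_true(all(rowSums(cc2) == 20))
  expect_error(confusion_counts(character(), character()),
               class = "fallsense_validation_error")
  expect_error(confusion_counts(truth, truth[-1]),
               class = "fallsense_validation_error")
})

test_that("macro metrics match a direct evaluation of their formulas", {
  truth <- rep(c("NON_FALL", "SLF", "FFH"), times = c(10, 5, 5))
  perfect <- macro_metrics(confusion_counts(truth, truth))
  expect_equal(unname(perfect), rep(1, 5))

  # degenerate single-class predictor: zero-denominator terms contribute 0
  single <- macro_metrics(confusion_counts(truth, rep("NON_FALL", 20)))
  expect_true(all(single >= 0 & single <= 1))
  expect_equal(single[["sensitivity"]], 1 / 3)  # only NON_FALL recalled

  # hand-built confusion table evaluated independently, cell by cell
  tp <- c(8, 3, 2); fn <- c(2, 2, 3); fp <- c(4, 1, 2); tn <- 20 - tp - fn - fp
  cc <- cbind(TP = tp, FP = fp, TN = tn, FN = fn)
  rownames(cc) <- c("NON_FALL", "SLF", "FFH")
  got <- macro_metrics(structure(cc, n = 20, class = c("confusion_counts", "matrix")))
  direct <- c(
    accuracy = mean((tp + tn) / 20),
    sensitivity = mean(tp / (tp + fn)),
    specificity = mean(tn / (tn + fp)),
    f1 = mean(2 * tp / (2 * tp + fp + fn)),
    mcc = mean((tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))))
  expect_equal(got, direct, tolerance = 1e-12)
  # MCC = 1 iff the confusion is diagonal
  expect_equal(perfect[["mcc"]], 1)
  expect_lt(got[["mcc"]], 1)
})

test_that("average precision behaves at its fixed points and null limit", {
  truth <- c("SLF", "NON_FALL", "NON_FALL", "FFH")
  scores <- rbind(c(0.1, 0.8, 0.1), c(0.9, 0.05, 0.05),
                  c(0.8, 0.1, 0.1), c(0.1, 0.1, 0.8))
  colnames(scores) <- c("NON_FALL", "SLF", "FFH")
  ap <- pr_auc_per_class(truth, scores)
  expect_equal(unname(ap), c(1, 1, 1))  # perfectly ranked

  # single positive ranked first
  t2 <- c("SLF", rep("NON_FALL", 9))
  s2 <- matrix(0.1, 10, 3, dimnames = list(NULL, c("NON_FALL", "SLF", "FFH")))
  s2[1, "SLF"] <- 0.9
  expect_equal(pr_auc_per_class(t2, s2)[["SLF"]], 1)
  expect_true(is.na(pr_auc_per_class(t2, s2)[["FFH"]]))  # absent class: missing

  # label-independent scores converge to prevalence
  set.seed(3)
  n <- 10000
  truth_big <- sample(c("NON_FALL", "SLF", "FFH"), n, TRUE, prob = c(0.7, 0.2, 0.1))
  sc <- matrix(runif(3 * n), n, 3)
  sc <- sc / rowSums(sc)
  colnames(sc) <- c("NON_FALL", "SLF", "FFH")
  ap_null <- pr_auc_per_class(truth_big, sc)
  prev <- table(factor(truth_big, levels = c("NON_FALL", "SLF", "FFH"))) / n
  expect_equal(unname(ap_null), as.vector(prev), tolerance = 0.02)
})

test_that("lead time converts detection-to-impact intervals to ms", {
  expect_equal(lead_time(4.5, 5.0), 500)
  expect_equal(lead_time(5.0 - free_fall_duration(2.0), 5.0), 638.5509,
               tolerance = 1e-3)
  expect_gt(lead_time(5.0 - free_fall_duration(0.5), 5.0), 130)
  expect_error(lead_time(5.1, 5.0), class = "fallsense_validation_error")
})

test_that("stratified CV keeps fold proportions and separable data near-perfect", {
  fm <- planted_fm(n = 300, seed = 4)
  rep_cv <- cross_validate(fm, k = 5, params = fast_params, seed = 2)
  expect_equal(nrow(rep_cv$folds), 5)
  f1_mean <- rep_cv$aggregate$mean[rep_cv$aggregate$metric == "f1"]
  expect_gte(f1_mean, 0.95)
  metrics <- rep_cv$folds[, c("accuracy", "sensitivity", "specificity", "f1")]
  expect_true(all(metrics >= 0 & metrics <= 1))
  expect_true(all(rep_cv$folds$mcc >= -1 & rep_cv$folds$mcc <= 1))
  expect_error(cross_validate(fm_rows(fm, 1:10), k = 5, params = fast_params),
               class = "fallsense_stratification_error")
})

test_that("shuffled labels drive CV macro-F1 to the chance level", {
  fm <- planted_fm(n = 300, seed = 6)
  set.seed(9)
  fm$x[, "f1"] <- rnorm(300)       # destroy the signal entirely
  fm$labels <- sample(fm$labels)
  rep_cv <- cross_validate(fm, k = 5, params = fast_params, seed = 2)
  f1_mean <- rep_cv$aggregate$mean[rep_cv$aggregate$metric == "f1"]
  expect_equal(f1_mean, 1 / 3, tolerance = 0.1)
})

test_that("evaluation never refits the model on test labels", {
  ps <- planted_setup()
  raw_before <- xgboost::xgb.save.raw(ps$model$booster)
  truth <- ps$val$labels
  m_true <- macro_metrics(confusion_counts(truth, predict(ps$model, ps$val)$labels))
  set.seed(1)
  m_perm <- macro_metrics(confusion_counts(sample(truth),
                                           predict(ps$model, ps$val)$labels))
  expect_false(isTRUE(all.equal(m_true, m_perm)))
  expect_identical(xgboost::xgb.save.raw(ps$model$booster), raw_before)
})

test_that("latency measurement reports positive per-window cost with host info", {
  ps <- planted_setup()
  lat <- measure_latency(ps$model, ps$val, repeats = 2)
  expect_gt(lat$ms_per_window, 0)
  expect_equal(lat$n_windows, nrow(ps$val$x))
  expect_true(nzchar(lat$host$r_version))
  expect_error(measure_latency(ps$model, fm_rows(ps$val, 1:50)),
               class = "fallsense_parameter_error")
})

test_that("ANOVA/Tukey comparison separates and groups models correctly", {
  same <- data.frame(model = rep(c("m1", "m2", "m3"), each = 5),
                     value = rep(0.9, 15))
  res0 <- compare_models(same)
  expect_equal(unname(res0$anova["F"]), 0)
  expect_false(any(res0$tukey$significant))

  set.seed(2)
  two <- data.frame(model = rep(c("good", "bad"), each = 5),
                    value = c(rep(0.9, 5), rep(0.5, 5)) + rnorm(10, 0, 0.005))
  res2 <- compare_models(two)
  expect_lt(res2$anova[["p"]], 0.05)
  expect_true(all(res2$tukey$significant))
  expect_match(res2$grouping, "^\\(good\\) > \\(bad\\)$")

  three <- data.frame(model = rep(c("a", "b", "c"), each = 5),
                      value = c(rep(0.9, 5), rep(0.89, 5), rep(0.5, 5)) +
                        rnorm(15, 0, 0.004))
  res3 <- compare_models(three)
  expect_equal(nrow(res3$tukey), 3)
  expect_error(compare_models(data.frame(model = "a", value = 1)),
               class = "fallsense_validation_error")
})
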