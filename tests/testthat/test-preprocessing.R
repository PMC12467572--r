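test_that("median filter matches hand-computed neighborhoods", {
  expect_equal(median_filter(c(1, 1, 9, 1, 1), kernel = 3), rep(1, 5))
  x <- rep(4.2, 20)
  expect_equal(median_filter(x, kernel = 5), x)      # constants are fixed points
  y <- rnorm(30)
  expect_equal(median_filter(y, kernel = 1), y)      # kernel 1 is identity
  expect_error(median_filter(y, kernel = 4), class = "fallsense_parameter_error")
  # idempotence on a step signal
  stp <- c(rep(0, 10), rep(1, 10))
  once <- median_filter(stp, kernel = 5)
  expect_equal(median_filter(once, kernel = 5), once)
})

test_that("SMV is the per-sample Euclidean norm", {
  expect_equal(compute_smv(0, 0, 1), 1)
  expect_equal(compute_smv(3, 4, 0), 5)
  expect_equal(compute_smv(0, 0, 0), 0)
})

test_that("segmentation enumerates full windows inside the active segment", {
  mk_rec <- function(n_active) {
    n <- 40 + n_active
    s <- data.frame(t = (seq_len(n) - 1) / 40, ax = 0, ay = 0, az = 1,
                    gx = 0, gy = 0, gz = 0)
    imu_recording(s, list(klass = "NON_FALL", subtype = "standing",
                          active_start = 1.0, active_end = (n - 1) / 40,
                          loss_of_balance_t = NA_real_, impact_t = NA_real_))
  }
  expect_length(segment_windows(mk_rec(120), stride = 40), 3)
  expect_length(segment_windows(mk_rec(100), stride = 40), 2)
  expect_length(segment_windows(mk_rec(80), stride = 20), 3)
  expect_length(segment_windows(mk_rec(39 + 1), stride = 40), 1)
  w <- segment_windows(mk_rec(120), stride = 40)[[1]]
  expect_equal(nrow(w$samples), 40)
  expect_equal(w$end_time, w$samples$t[40])
})

test_that("window labeling follows the half-open critical-phase rule", {
  ann <- list(klass = "FFH", subtype = "x", active_start = 0, active_end = 10,
              loss_of_balance_t = 5.0, impact_t = 5.6)
  lab <- function(end_time) {
    out <- label_windows(list(stub_window(end_time)), ann)
    if (length(out) == 0) return(NA_character_)
    as.character(out[[1]]$label)
  }
  expect_equal(lab(5.1), "FFH")          # ends 0.1 s after balance loss
  expect_equal(lab(4.9), "NON_FALL")     # ends before balance loss
  expect_true(is.na(lab(5.6)))           # ends exactly at impact: discarded
  expect_true(is.na(lab(6.0)))           # post-fall phase: discarded
  nf_ann <- list(klass = "NON_FALL", subtype = "x", active_start = 0,
                 active_end = 10, loss_of_balance_t = NA, impact_t = NA)
  expect_equal(as.character(label_windows(list(stub_window(3)), nf_ann)[[1]]$label),
               "NON_FALL")
  expect_error(label_windows(list(stub_window(3)), NULL),
               class = "fallsense_annotation_error")
})

test_that("every fall recording yields fall windows and none past impact", {
  wins <- small_windows()
  labels <- vapply(wins, function(w) as.character(w$label), "")
  expect_setequal(unique(labels), c("NON_FALL", "SLF", "FFH"))
  expect_equal(sum(labels == "SLF"), 16)   # one critical window per fall recording
  expect_equal(sum(labels == "FFH"), 8)
})

test_that("augmentation emits three marked copies per window, deterministically", {
  wins <- small_windows()[1:6]
  aug <- augment_windows(wins, level = 2, seed = 9)
  expect_length(aug, 4 * 6)
  origins <- vapply(aug, function(w) w$origin, "")
  expect_equal(sum(origins == "augmented"), 18)
  expect_equal(vapply(aug, function(w) as.character(w$label), "")[7:24],
               rep(vapply(wins, function(w) as.character(w$label), ""), each = 3)[1:18])
  aug2 <- augment_windows(wins, level = 2, seed = 9)
  expect_identical(aug, aug2)
  expect_error(augment_windows(wins, level = 5, seed = 1),
               class = "fallsense_parameter_error")
  # every augmented window still has 40 samples on the original time grid
  for (w in aug) {
    expect_equal(nrow(w$window$samples), 40)
  }
})

test_that("level-1 jitter adds noise near its nominal 0.01 g sigma", {
  base <- small_windows()[[1]]
  const <- base
  const$window$samples[, c("ax", "ay", "az")] <- c(0, 0, 1)[col(matrix(0, 40, 3))]
  const$window$samples[, c("gx", "gy", "gz")] <- 0
  aug <- augment_windows(list(const), level = 1, seed = 21)
  jit <- aug[[2]]$window$samples  # first augmented copy is the jittered one
  sd_acc <- stats::sd(jit$az - 1)
  expect_lt(sd_acc, 3 * 0.01)
  expect_gt(sd_acc, 0.01 / 3)
})

test_that("stratified split uses largest-remainder counts and partitions", {
  wins <- small_windows()
  labels <- vapply(wins, function(w) as.character(w$label), "")
  sp <- stratified_split(wins, test_fraction = 0.2, seed = 3)
  te_lab <- vapply(sp$test, function(w) as.character(w$label), "")
  n_c <- table(factor(labels, levels = c("NON_FALL", "SLF", "FFH")))
  te_c <- table(factor(te_lab, levels = names(n_c)))
  # per-class counts within one window of round(n_c * fraction), exact total
  expect_true(all(abs(as.vector(te_c) - round(as.vector(n_c) * 0.2)) <= 1))
  expect_equal(sum(te_c), round(length(wins) * 0.2))
  expect_equal(length(sp$train) + length(sp$test), length(wins))
  # a clean case reproduces the per-class rounding exactly
  sub <- c(wins[which(labels == "NON_FALL")[1:100]],
           wins[which(labels == "SLF")[1:10]],
           wins[which(labels == "FFH")[1:5]])
  te2 <- table(factor(vapply(stratified_split(sub, 0.2, seed = 1)$test,
                             function(w) as.character(w$label), ""),
                      levels = names(n_c)))
  expect_equal(as.vector(te2), c(20, 2, 1))
  # augmented windows never reach the test side
  aug <- augment_windows(wins[1:10], level = 1, seed = 1)
  sp2 <- stratified_split(c(aug, wins[11:length(wins)]), 0.3, seed = 4)
  expect_true(all(vapply(sp2$test, function(w) w$origin, "") == "real"))
  expect_error(stratified_split(wins, 1.2), class = "fallsense_parameter_error")
})
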