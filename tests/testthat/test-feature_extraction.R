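# Independent direct-summation moment oracle used throughout this file.
oracle_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(min = min(x), mean = mu, max = max(x), var = m2, std = sqrt(m2),
    skew = if (m2 >= 1e-12) m3 / m2^1.5 else 0,
    kurt = if (m2 >= 1e-12) m4 / m2^2 - 3 else 0)
}

test_that("registry enumerates 24 channels x 7 stats = 168 names", {
  reg <- feature_registry()
  expect_length(reg, 168)
  expect_length(unique(reg), 168)
  expect_true(all(grepl("__", reg)))
  expect_equal(sum(grepl("^(ax|ay|az|gx|gy|gz)__", reg)), 42)    # 6 raw
  expect_equal(sum(grepl("(accel|roll|pitch)", reg)), 70)        # 10 accel-derived
  expect_equal(sum(grepl("gyro", reg)), 56)                      # 8 gyro-derived
})

test_that("stage-1 channels honor their closed forms on canonical samples", {
  # gravity-aligned rest
  m <- matrix(rep(c(0, 0, 1, 0, 0, 0), each = 40), 40, 6)
  colnames(m) <- c("ax", "ay", "az", "gx", "gy", "gz")
  s1 <- stage1_series(m)
  expect_equal(unique(s1$smv_accel), 1)
  expect_equal(unique(s1$roll), 0)
  expect_equal(unique(s1$pitch), 0)
  expect_equal(unique(s1$axmean_accel), 1 / 3)
  expect_equal(unique(s1$axrange_accel), 1)
  # x-axis gravity: pitch = atan2(-1, 0) = -90 deg
  m2 <- m; m2[, "ax"] <- 1; m2[, "az"] <- 0
  s2 <- stage1_series(m2)
  expect_equal(unique(s2$pitch), -90)
  expect_equal(unique(s2$smv_accel), 1)
  expect_equal(unique(s2$sma_accel), 1)
  # all-zero free-fall degenerate: every channel 0, atan2(0,0) := 0
  z <- stage1_series(matrix(0, 40, 6, dimnames = list(NULL, colnames(m))))
  expect_true(all(as.matrix(z) == 0))
})

test_that("stage-1 invariants hold on random windows", {
  for (seed in 1:5) {
    s1 <- stage1_series(random_window(seed))
    for (sensor in c("accel", "gyro")) {
      mn <- s1[[paste0("axmin_", sensor)]]
      mu <- s1[[paste0("axmean_", sensor)]]
      mx <- s1[[paste0("axmax_", sensor)]]
      expect_true(all(mn <= mu + 1e-12 & mu <= mx + 1e-12))
      expect_equal(s1[[paste0("axrange_", sensor)]], mx - mn)
      expect_equal(s1[[paste0("axvar_", sensor)]],
                   s1[[paste0("axstd_", sensor)]]^2)
      expect_true(all(s1[[paste0("smv_", sensor)]] >= 0))
      expect_true(all(s1[[paste0("sma_", sensor)]] >=
                        s1[[paste0("smv_", sensor)]] - 1e-12))  # L1 >= L2
    }
  }
})

test_that("stage-2 statistics equal the direct-summation oracle", {
  expect_equal(stage2_stats(rep(3.7, 40)),
               c(min = 3.7, mean = 3.7, max = 3.7, var = 0, std = 0,
                 skew = 0, kurt = 0))
  sym <- rep(c(-1, 0, 1, 0), 10)
  expect_equal(stage2_stats(sym)[["skew"]], 0)
  sparse <- c(rep(0, 37), rep(1, 3))
  expect_equal(stage2_stats(sparse), oracle_stats(sparse), tolerance = 1e-12)
})

test_that("extracted vectors are 168-dimensional and internally consistent", {
  fv <- extract_features(random_window(3))
  expect_length(fv, 168)
  expect_identical(names(fv), feature_registry())
  expect_true(all(is.finite(fv)))
  for (ch in c("smv_accel", "gx", "roll")) {
    expect_equal(fv[[paste0(ch, "__var")]], fv[[paste0(ch, "__std")]]^2)
    expect_lte(fv[[paste0(ch, "__min")]], fv[[paste0(ch, "__mean")]])
    expect_lte(fv[[paste0(ch, "__mean")]], fv[[paste0(ch, "__max")]])
  }
  # constant gravity window
  m <- matrix(rep(c(0, 0, 1, 0, 0, 0), each = 40), 40, 6,
              dimnames = list(NULL, c("ax", "ay", "az", "gx", "gy", "gz")))
  fg <- extract_features(m)
  expect_equal(fg[["smv_accel__mean"]], 1)
  expect_true(all(fg[grepl("__var$", names(fg))] == 0))
})

test_that("features are invariant to time permutation of the samples", {
  m <- random_window(8)
  set.seed(1)
  perm <- m[sample(40), ]
  expect_equal(extract_features(m), extract_features(perm), tolerance = 1e-12)
})

test_that("scaling acceleration scales SMV stats but not orientation", {
  m <- random_window(12)
  m2 <- m
  m2[, 1:3] <- 3 * m2[, 1:3]
  f1 <- extract_features(m)
  f2 <- extract_features(m2)
  expect_equal(f2[["smv_accel__mean"]], 3 * f1[["smv_accel__mean"]])
  expect_equal(f2[["roll__mean"]], f1[["roll__mean"]])
  expect_equal(f2[["pitch__max"]], f1[["pitch__max"]])
})

test_that("bulk extraction matches the per-window path and tallies counts", {
  wins <- small_windows()
  fm <- build_feature_matrix(wins)
  expect_equal(dim(fm$x), c(length(wins), 168))
  expect_equal(sum(fm$n_c), length(wins))
  i <- c(1, 25, length(wins))
  for (j in i) {
    expect_equal(fm$x[j, ], extract_features(wins[[j]]$window), tolerance = 1e-12)
  }
  single <- build_feature_matrix(wins[1])
  expect_equal(dim(single$x), c(1, 168))
  expect_error(build_feature_matrix(list()), class = "fallsense_validation_error")
})
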