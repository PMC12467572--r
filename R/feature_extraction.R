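# Two-stage feature extraction: each 40 x 6 window is expanded into 24
# per-time-step channels (stage 1), and each channel is summarized by 7
# descriptive statistics over the window (stage 2), giving the canonical
# 168-dimensional feature vector.
#
# Channel accounting (the unique natural reading of the printed total):
#   6  raw axes                     ax ay az gx gy gz
#   10 accelerometer-derived        smv sma axmin axmean axmax axrange
#                                   axstd axvar roll pitch
#   8  gyroscope-derived            smv sma axmin axmean axmax axrange
#                                   axstd axvar
#   = 24 channels x 7 stats = 168.
# Roll/pitch are gravity-referenced and therefore accelerometer-only.
# All variances are population variances (divide by n), both across the 3
# axes at each time step and across the 40 samples of the window.

STAGE2_STATS <- c("min", "mean", "max", "var", "std", "skew", "kurt")

STAGE1_CHANNELS <- c(
  "ax", "ay", "az", "gx", "gy", "gz",
  "smv_accel", "sma_accel", "axmin_accel", "axmean_accel", "axmax_accel",
  "axrange_accel", "axstd_accel", "axvar_accel", "roll", "pitch",
  "smv_gyro", "sma_gyro", "axmin_gyro", "axmean_gyro", "axmax_gyro",
  "axrange_gyro", "axstd_gyro", "axvar_gyro")

#' Canonical 168-name feature registry
#'
#' Feature names are `<channel>__<stat>` over the 24 stage-1 channels and
#' the 7 stage-2 statistics, in a frozen order. Selection results are always
#' reported by these names, never by index.
#'
#' @return Character vector of length 168.
#' @export
feature_registry <- function() {
  as.vector(t(outer(STAGE1_CHANNELS, STAGE2_STATS, paste, sep = "__")))
}

# Core vectorized extractor over an array of windows.
# arr: 40 x 6 x n array (channel order ax ay az gx gy gz).
# Returns n x 168 matrix with registry column names.
features_from_array <- function(arr) {
  n <- dim(arr)[3]
  len <- dim(arr)[1]
  chans <- vector("list", 24)
  names(chans) <- STAGE1_CHANNELS
  for (k in 1:6) chans[[k]] <- matrix(arr[, k, ], len, n)
  for (sensor in c("accel", "gyro")) {
    o <- if (sensor == "accel") 0L else 3L
    a1 <- chans[[o + 1L]]; a2 <- chans[[o + 2L]]; a3 <- chans[[o + 3L]]
    mn <- pmin(a1, a2, a3); mx <- pmax(a1, a2, a3)
    mu <- (a1 + a2 + a3) / 3
    v <- ((a1 - mu)^2 + (a2 - mu)^2 + (a3 - mu)^2) / 3  # population, n = 3
    chans[[paste0("smv_", sensor)]] <- sqrt(a1^2 + a2^2 + a3^2)
    chans[[paste0("sma_", sensor)]] <- abs(a1) + abs(a2) + abs(a3)
    chans[[paste0("axmin_", sensor)]] <- mn
    chans[[paste0("axmean_", sensor)]] <- mu
    chans[[paste0("axmax_", sensor)]] <- mx
    chans[[paste0("axrange_", sensor)]] <- mx - mn
    chans[[paste0("axstd_", sensor)]] <- sqrt(v)
    chans[[paste0("axvar_", sensor)]] <- v
  }
  # gravity-referenced orientation; atan2(0, 0) = 0 keeps free fall finite
  chans[["roll"]] <- atan2(chans[["ay"]], chans[["az"]]) * 180 / pi
  chans[["pitch"]] <- atan2(-chans[["ax"]],
                            sqrt(chans[["ay"]]^2 + chans[["az"]]^2)) * 180 / pi

  out <- matrix(NA_real_, n, 24L * 7L)
  for (ci in seq_along(STAGE1_CHANNELS)) {
    m <- chans[[ci]]
    mins <- col_min(m); maxs <- col_max(m)
    mu <- colMeans(m)
    d <- m - rep(mu, each = len)
    m2 <- colMeans(d^2)
    m3 <- colMeans(d^3)
    m4 <- colMeans(d^4)
    std <- sqrt(m2)
    ok <- m2 >= 1e-12
    skew <- ifelse(ok, m3 / m2^1.5, 0)
    kurt <- ifelse(ok, m4 / m2^2 - 3, 0)
    out[, (ci - 1L) * 7L + 1:7] <- cbind(mins, mu, maxs, m2, std, skew, kurt)
  }
  colnames(out) <- feature_registry()
  out
}

#' Stage-1 per-time-step channel series for one window
#'
#' Expands the raw 40 x 6 block into the 24 named channels: the raw axes,
#' per-sensor cross-axis statistics at each time step (L2 norm SMV, L1
#' magnitude SMA, min/mean/max/range and population std/var over the 3 axis
#' values), and accelerometer-derived roll/pitch in degrees
#' (`roll = atan2(ay, az)`, `pitch = atan2(-ax, sqrt(ay^2 + az^2))`).
#'
#' @param window An `imu_window`, or a 40 x 6 matrix/data frame with columns
#'   `ax, ay, az, gx, gy, gz`.
#' @return Data frame of 40 rows and 24 named channel columns.
#' @export
stage1_series <- function(window) {
  m <- window_matrix(window)
  chans <- list()
  chans[["ax"]] <- m[, 1]; chans[["ay"]] <- m[, 2]; chans[["az"]] <- m[, 3]
  chans[["gx"]] <- m[, 4]; chans[["gy"]] <- m[, 5]; chans[["gz"]] <- m[, 6]
  for (sensor in c("accel", "gyro")) {
    o <- if (sensor == "accel") 0L else 3L
    a <- m[, o + 1:3, drop = FALSE]
    mu <- rowMeans(a)
    v <- rowMeans((a - mu)^2)
    chans[[paste0("smv_", sensor)]] <- sqrt(rowSums(a^2))
    chans[[paste0("sma_", sensor)]] <- rowSums(abs(a))
    chans[[paste0("axmin_", sensor)]] <- do.call(pmin, as.data.frame(a))
    chans[[paste0("axmean_", sensor)]] <- mu
    chans[[paste0("axmax_", sensor)]] <- do.call(pmax, as.data.frame(a))
    chans[[paste0("axrange_", sensor)]] <- chans[[paste0("axmax_", sensor)]] -
      chans[[paste0("axmin_", sensor)]]
    chans[[paste0("axstd_", sensor)]] <- sqrt(v)
    chans[[paste0("axvar_", sensor)]] <- v
  }
  chans[["roll"]] <- atan2(m[, 2], m[, 3]) * 180 / pi
  chans[["pitch"]] <- atan2(-m[, 1], sqrt(m[, 2]^2 + m[, 3]^2)) * 180 / pi
  as.data.frame(chans)[, STAGE1_CHANNELS]
}

window_matrix <- function(window) {
  if (inherits(window, "imu_window")) {
    as.matrix(window$samples[, c("ax", "ay", "az", "gx", "gy", "gz")])
  } else {
    m <- as.matrix(window)
    if (!is.null(colnames(m)) &&
        all(c("ax", "ay", "az", "gx", "gy", "gz") %in% colnames(m))) {
      m <- m[, c("ax", "ay", "az", "gx", "gy", "gz")]
    }
    stopifnot(ncol(m) == 6)
    m
  }
}

#' Stage-2 descriptive statistics of a series
#'
#' Population moments over the window: min, mean, max, variance, standard
#' deviation, Fisher-Pearson skewness `m3 / m2^1.5` and excess kurtosis
#' `m4 / m2^2 - 3`. When the series is (numerically) constant
#' (`m2 < 1e-12`) skewness and kurtosis are defined as 0.
#'
#' @param x Numeric series (finite values).
#' @return Named numeric vector `min, mean, max, var, std, skew, kurt`.
#' @export
stage2_stats <- function(x) {
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  c(min = min(x), mean = mu, max = max(x), var = m2, std = sqrt(m2),
    skew = if (m2 >= 1e-12) m3 / m2^1.5 else 0,
    kurt = if (m2 >= 1e-12) m4 / m2^2 - 3 else 0)
}

#' Extract the 168-dimensional feature vector of one window
#'
#' Applies [stage2_stats()] to each of the 24 [stage1_series()] channels in
#' the canonical registry order.
#'
#' @param window An `imu_window` or 40 x 6 block.
#' @return Named numeric vector of length 168.
#' @export
extract_features <- function(window) {
  m <- window_matrix(window)
  features_from_array(array(m, c(nrow(m), 6L, 1L)))[1, ]
}

#' Build a feature matrix from labeled windows
#'
#' @param lwindows Non-empty list of labeled windows (from
#'   [label_windows()] / [augment_windows()]).
#' @return A `feature_matrix`: list with `x` (n x 168 matrix, registry
#'   column order), `labels` (factor over NON_FALL/SLF/FFH), `origin`,
#'   `end_times`, `source_ids`, and per-class counts `n_c`.
#' @export
build_feature_matrix <- function(lwindows) {
  if (length(lwindows) == 0) fs_validation_error("cannot build a feature matrix from 0 windows")
  n <- length(lwindows)
  arr <- array(NA_real_, c(WINDOW_LEN, 6L, n))
  for (i in seq_len(n)) arr[, , i] <- window_matrix(lwindows[[i]]$window)
  x <- features_from_array(arr)
  if (any(!is.finite(x))) fs_validation_error("non-finite feature value encountered")
  labels <- as_class_factor(vapply(lwindows, function(w) as.character(w$label), ""))
  structure(list(
    x = x,
    labels = labels,
    origin = vapply(lwindows, function(w) w$origin, ""),
    end_times = vapply(lwindows, function(w) w$window$end_time, 0),
    source_ids = vapply(lwindows, function(w) w$window$source_id, ""),
    n_c = table(labels)),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features; counts %s\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s=%d", names(x$n_c), x$n_c), collapse = ", ")))
  invisible(x)
}

# Internal: subset a feature_matrix by row index or feature names.
fm_subset <- function(fm, rows = NULL, features = NULL) {
  out <- fm
  if (!is.null(rows)) {
    out$x <- out$x[rows, , drop = FALSE]
    out$labels <- out$labels[rows]
    out$origin <- out$origin[rows]
    out$end_times <- out$end_times[rows]
    out$source_ids <- out$source_ids[rows]
    out$n_c <- table(out$labels)
  }
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(out$x))
    if (length(missing)) {
      fs_registry_error(sprintf("unknown feature name(s): %s",
                                paste(missing, collapse = ", ")))
    }
    out$x <- out$x[, features, drop = FALSE]
  }
  out
}
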