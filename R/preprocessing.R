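# Window segmentation, median denoising, SMV, critical-phase labeling,
# training-set augmentation and stratified splitting.
#
# Windows are fixed at 40 samples (1 s at 40 Hz). A window from a fall
# recording is labeled with the fall class iff its LAST sample time lies in
# the half-open critical phase [loss_of_balance_t, impact_t); windows ending
# at or after impact belong to the post-fall phase and are discarded.

WINDOW_LEN <- 40L

#' Moving median filter with reflection padding
#'
#' Each output value is the median of the kernel-sized neighborhood; the
#' series is reflected at both edges so output length equals input length.
#' With a data frame input the filter is applied independently to every
#' non-time column.
#'
#' @param x Numeric vector, or a sample data frame (columns other than `t`
#'   are filtered).
#' @param kernel Odd integer kernel width, between 1 and the series length.
#'   Default 5 samples (125 ms at 40 Hz): removes single-sample spikes while
#'   preserving the sub-20 Hz band of human motion.
#' @return Filtered object of the same shape as `x`.
#' @export
median_filter <- function(x, kernel = 5L) {
  if (is.data.frame(x)) {
    for (col in setdiff(names(x), "t")) x[[col]] <- median_filter(x[[col]], kernel)
    return(x)
  }
  kernel <- as.integer(kernel)
  n <- length(x)
  if (kernel %% 2L == 0L || kernel < 1L || kernel > n) {
    fs_parameter_error(sprintf("kernel must be an odd integer in [1, %d], got %d", n, kernel))
  }
  if (kernel == 1L) return(x)
  h <- kernel %/% 2L
  xp <- c(x[h:1], x, x[n:(n - h + 1)])
  # running median over the reflected series; edge positions are trimmed off
  stats::runmed(xp, kernel, endrule = "keep")[(h + 1L):(n + h)]
}

#' Accelerometer sum magnitude vector
#'
#' Per-sample Euclidean norm `sqrt(ax^2 + ay^2 + az^2)` in g: ~1 g at rest,
#' near 0 g in free fall, spiking at impact.
#'
#' @param ax,ay,az Accelerometer axis series in g, or `ax` may be a data
#'   frame/matrix with columns `ax, ay, az`.
#' @return Numeric SMV series.
#' @export
compute_smv <- function(ax, ay = NULL, az = NULL) {
  if (is.null(ay)) {
    m <- ax
    return(sqrt(m[, "ax"]^2 + m[, "ay"]^2 + m[, "az"]^2))
  }
  sqrt(ax^2 + ay^2 + az^2)
}

#' Segment a recording into fixed 40-sample windows
#'
#' Windows start at `active_start + k * stride` samples and must lie fully
#' inside the active segment; a partial tail is dropped. The training
#' pipeline uses non-overlapping windows (`stride = 40`) to avoid leakage
#' between near-duplicate windows; detection replay uses `stride = 1`.
#'
#' @param rec An `imu_recording`.
#' @param stride Positive integer stride in samples.
#' @param filter_kernel Median-filter kernel applied per window (odd integer,
#'   or `NULL` to skip).
#' @return List of `imu_window` objects (possibly empty).
#' @export
segment_windows <- function(rec, stride = WINDOW_LEN, filter_kernel = 5L) {
  stopifnot(inherits(rec, "imu_recording"))
  stride <- as.integer(stride)
  if (stride < 1L) fs_parameter_error("stride must be >= 1")
  s <- rec$samples
  ann <- rec$annotation
  in_seg <- which(s$t >= ann$active_start - TIME_TOL_S &
                    s$t <= ann$active_end + TIME_TOL_S)
  if (length(in_seg) < WINDOW_LEN) return(list())
  i0 <- in_seg[1]
  i_last <- in_seg[length(in_seg)]
  starts <- seq.int(i0, i_last - WINDOW_LEN + 1L, by = stride)
  lapply(starts, function(st) {
    sl <- s[st:(st + WINDOW_LEN - 1L), , drop = FALSE]
    rownames(sl) <- NULL
    if (!is.null(filter_kernel)) sl <- median_filter(sl, filter_kernel)
    structure(list(source_id = rec$recording_id,
                   start_index = st,
                   samples = sl,
                   end_time = sl$t[WINDOW_LEN]),
              class = "imu_window")
  })
}

#' Label windows from their recording's annotation
#'
#' For SLF/FFH recordings a window gets the fall label iff its last sample
#' time lies in `[loss_of_balance_t, impact_t)`; windows ending before
#' balance loss are NON_FALL; windows ending at or after impact (post-fall
#' phase) are discarded. All windows of a NON_FALL recording are NON_FALL.
#'
#' @param windows List of `imu_window` from [segment_windows()].
#' @param annotation The recording's annotation list.
#' @return List of labeled windows: each a list with `window`, `label`
#'   (factor over NON_FALL/SLF/FFH) and `origin = "real"`.
#' @export
label_windows <- function(windows, annotation) {
  if (is.null(annotation) || is.null(annotation$klass)) {
    fs_annotation_error("annotation is required to label windows")
  }
  lw <- function(w, label) list(window = w, label = as_class_factor(label), origin = "real")
  if (annotation$klass == "NON_FALL") {
    return(lapply(windows, lw, label = "NON_FALL"))
  }
  out <- list()
  for (w in windows) {
    te <- w$end_time
    if (te < annotation$loss_of_balance_t - TIME_TOL_S) {
      out[[length(out) + 1L]] <- lw(w, "NON_FALL")
    } else if (te < annotation$impact_t - TIME_TOL_S) {
      out[[length(out) + 1L]] <- lw(w, annotation$klass)
    } # else: post-fall phase, discarded
  }
  out
}

#' Windows for a whole dataset
#'
#' Convenience wrapper: segments and labels every recording with the
#' training stride.
#'
#' @param recordings List of `imu_recording`.
#' @inheritParams segment_windows
#' @return Flat list of labeled windows.
#' @export
windows_from_recordings <- function(recordings, stride = WINDOW_LEN,
                                    filter_kernel = 5L) {
  out <- lapply(recordings, function(rec) {
    label_windows(segment_windows(rec, stride, filter_kernel), rec$annotation)
  })
  do.call(c, out)
}

# Monotone time warp: 4 interior knots displaced by N(0, 0.05 * level) of the
# window duration, monotone cubic (Hyman) map, cubic resampling back to the
# 40-sample grid.
warp_window <- function(m, level) {
  n <- nrow(m)
  u <- seq(0, 1, length.out = 6)
  disp <- stats::rnorm(4, 0, 0.05 * level)
  knots <- u
  knots[2:5] <- u[2:5] + disp
  knots <- cummax(pmin(pmax(knots, 0), 1))
  knots[1] <- 0; knots[6] <- 1
  if (any(diff(knots) <= 0)) knots <- u  # degenerate displacement: identity map
  tmap <- stats::splinefun(u, knots, method = "hyman")
  src <- tmap(seq(0, 1, length.out = n)) * (n - 1) + 1
  apply(m, 2, function(col) stats::spline(seq_len(n), col, xout = src)$y)
}

#' Augment labeled training windows
#'
#' For each input window emits three transformed copies — jittering, scaling
#' and temporal warping — at the requested intensity level, keeping the
#' label and marking `origin = "augmented"`. Level `L` in 1..4 maps to jitter
#' sigma `0.01 L` g (accelerometer) and `L` deg/s (gyroscope), a single
#' scaling factor drawn from U(1 - 0.05 L, 1 + 0.05 L), and warp knot
#' displacement sigma `0.05 L` of the window duration.
#'
#' @param train List of labeled windows (the training portion only).
#' @param level Intensity level, integer 1..4.
#' @param seed Integer seed; output is deterministic in `(train, level, seed)`.
#' @return List of `4n` labeled windows: the `n` originals followed by `3n`
#'   augmented copies.
#' @export
augment_windows <- function(train, level = 1L, seed = 1L) {
  level <- as.integer(level)
  if (!level %in% 1:4) fs_parameter_error("augmentation level must be in 1..4")
  set.seed(as.integer(seed))
  chan <- c("ax", "ay", "az", "gx", "gy", "gz")
  aug <- list()
  for (lwin in train) {
    w <- lwin$window
    m <- as.matrix(w$samples[, chan])
    jit <- m
    jit[, 1:3] <- jit[, 1:3] + stats::rnorm(3 * WINDOW_LEN, 0, 0.01 * level)
    jit[, 4:6] <- jit[, 4:6] + stats::rnorm(3 * WINDOW_LEN, 0, 1 * level)
    sc <- m * stats::runif(1, 1 - 0.05 * level, 1 + 0.05 * level)
    wp <- warp_window(m, level)
    for (mm in list(jit, sc, wp)) {
      s2 <- w$samples
      s2[, chan] <- mm
      w2 <- structure(list(source_id = w$source_id, start_index = w$start_index,
                           samples = s2, end_time = w$end_time),
                      class = "imu_window")
      aug[[length(aug) + 1L]] <- list(window = w2, label = lwin$label,
                                      origin = "augmented")
    }
  }
  c(train, aug)
}

#' Stratified train/test split of labeled windows
#'
#' Original windows are partitioned per class with largest-remainder rounding
#' of `round(class count * test_fraction)` so totals match; augmented windows
#' (if present in the input) always go to the training side.
#'
#' @param windows List of labeled windows.
#' @param test_fraction Fraction in (0, 1); default 0.2.
#' @param seed Integer seed for the per-class sampling.
#' @return List with elements `train` and `test`.
#' @export
stratified_split <- function(windows, test_fraction = 0.2, seed = 1L) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    fs_parameter_error("test_fraction must be strictly between 0 and 1")
  }
  origin <- vapply(windows, function(w) w$origin, "")
  labels <- vapply(windows, function(w) as.character(w$label), "")
  orig_idx <- which(origin == "real")
  tab <- table(factor(labels[orig_idx], levels = CLASSES))
  if (any(tab < 2)) {
    fs_stratification_error(sprintf(
      "every class needs >= 2 original windows for a stratified split (counts: %s)",
      paste(tab, collapse = "/")))
  }
  test_counts <- largest_remainder(as.numeric(tab), test_fraction)
  names(test_counts) <- names(tab)
  set.seed(as.integer(seed))
  test_idx <- integer()
  for (kl in CLASSES) {
    pool <- orig_idx[labels[orig_idx] == kl]
    test_idx <- c(test_idx, sort(sample(pool, test_counts[[kl]])))
  }
  train_idx <- setdiff(seq_along(windows), test_idx)
  list(train = windows[train_idx], test = windows[sort(test_idx)])
}
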