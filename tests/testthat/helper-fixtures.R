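# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small, fast hyperparameters inside the published search bounds.
fast_params <- list(learning_rate = 0.1, n_rounds = 120L, max_depth = 4L,
                    subsample = 0.9, colsample_bytree = 0.8, gamma = 0,
                    min_child_weight = 1L, reg_alpha = 1e-6, reg_lambda = 1e-6)

# Feature matrix with one decisive feature (f1), pure-noise features and a
# constant column; classes perfectly separated along f1.
planted_fm <- function(n = 600, n_noise = 20, seed = 0, sep = 3) {
  set.seed(seed)
  y <- factor(rep(c("NON_FALL", "SLF", "FFH"), length.out = n),
              levels = c("NON_FALL", "SLF", "FFH"))
  x <- matrix(rnorm(n * (n_noise + 1)), n, n_noise + 1)
  colnames(x) <- c("f1", paste0("noise", seq_len(n_noise)))
  x[, "f1"] <- as.integer(y) * sep + rnorm(n, 0, 0.3)
  x <- cbind(x, const = 1)
  structure(list(x = x, labels = y, origin = rep("real", n),
                 end_times = rep(1, n), source_ids = rep("synthetic", n),
                 n_c = table(y)),
            class = "feature_matrix")
}

fm_rows <- function(fm, rows) fallsense:::fm_subset(fm, rows = rows)

# Planted dataset with a fitted model and train/val split, shared across
# selection and evaluation tests.
planted_setup <- function() {
  fixture("planted_setup", function() {
    fm <- planted_fm(n = 600, seed = 0)
    set.seed(1)
    idx <- sort(sample(600, 450))
    train <- fm_rows(fm, idx)
    val <- fm_rows(fm, setdiff(seq_len(600), idx))
    model <- fit_booster(train, params = fast_params, seed = 1)
    list(fm = fm, train = train, val = val, model = model)
  })
}

# A small labeled-window dataset from the synthetic generator.
small_windows <- function() {
  fixture("small_windows", function() {
    spec <- generator_spec(class_totals = c(NON_FALL = 60, SLF = 16, FFH = 8),
                           seed = 42)
    windows_from_recordings(generate_dataset(spec))
  })
}

# Build a bare imu_window carrying only what label_windows() consumes.
stub_window <- function(end_time) {
  structure(list(source_id = "stub", start_index = 1L,
                 samples = NULL, end_time = end_time),
            class = "imu_window")
}

# A valid random 40 x 6 window (finite, in sensor range).
random_window <- function(seed) {
  set.seed(seed)
  m <- cbind(matrix(rnorm(120, 0, 0.5), 40, 3),
             matrix(rnorm(120, 0, 50), 40, 3))
  colnames(m) <- c("ax", "ay", "az", "gx", "gy", "gz")
  m
}
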