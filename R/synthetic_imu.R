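# Synthetic annotated IMU recordings emulating the three study classes:
# non-fall construction activities, same-level-fall (SLF) critical phases
# (~0.3-0.5 s between balance loss and impact) and fall-from-height (FFH)
# critical phases whose duration follows free-fall physics for drops of
# 0.5-2 m. Only SMV/orientation-level morphology is emulated: downstream
# stages consume fixed windows and window statistics, not raw kinematics.

GRAVITY_MS2 <- 9.81

#' Free-fall duration for a given drop height
#'
#' Closed-form ballistic fall time `sqrt(2 h / g)` with `g` = 9.81 m/s^2.
#' The critical phase of a generated FFH recording has exactly this duration
#' (rounded to the 40 Hz sample grid).
#'
#' @param height_m Drop height in meters (> 0).
#' @return Duration in seconds.
#' @examples
#' free_fall_duration(2.0) # ~0.64 s
#' @export
free_fall_duration <- function(height_m) {
  if (!is.numeric(height_m) || any(!is.finite(height_m)) || any(height_m <= 0)) {
    fs_domain_error("height_m must be a positive finite number")
  }
  sqrt(2 * height_m / GRAVITY_MS2)
}

#' Default subtype parameter table
#'
#' One row per activity subtype the generator knows: 13 non-fall activities
#' (stationary, locomotion, lifting, high-vibration tool use at 12-18 Hz and
#' jumps), 10 SLF variants with critical-phase durations in 0.30-0.50 s, and
#' 8 FFH variants (forward/backward from 0.5, 0.7, 0.85 and 2.0 m). All
#' amplitudes/frequencies are synthetic defaults chosen for morphological
#' plausibility, not biomechanical measurements.
#'
#' @return Data frame with columns `klass`, `subtype`, `base_amp` (g),
#'   `base_freq` (Hz), `vib_freq` (Hz or NA), `vib_amp` (g), `jump`
#'   (logical), `critical_s` (s, SLF only), `height_m` (m, FFH only),
#'   `noise_sd` (g), `tilt_axis` (`"pitch"`/`"roll"`), `tilt_sign`.
#' @export
default_subtypes <- function() {
  nf <- function(subtype, base_amp, base_freq, vib_freq = NA, vib_amp = 0,
                 jump = FALSE, noise_sd = 0.03) {
    data.frame(klass = "NON_FALL", subtype = subtype, base_amp = base_amp,
               base_freq = base_freq, vib_freq = vib_freq, vib_amp = vib_amp,
               jump = jump, critical_s = NA_real_, height_m = NA_real_,
               noise_sd = noise_sd, tilt_axis = NA_character_, tilt_sign = NA_real_)
  }
  slf <- function(subtype, critical_s, tilt_axis, tilt_sign) {
    data.frame(klass = "SLF", subtype = subtype, base_amp = 0.15,
               base_freq = 1.8, vib_freq = NA, vib_amp = 0, jump = FALSE,
               critical_s = critical_s, height_m = NA_real_, noise_sd = 0.03,
               tilt_axis = tilt_axis, tilt_sign = tilt_sign)
  }
  ffh <- function(subtype, height_m, tilt_sign) {
    data.frame(klass = "FFH", subtype = subtype, base_amp = 0.05,
               base_freq = 1.2, vib_freq = NA, vib_amp = 0, jump = FALSE,
               critical_s = NA_real_, height_m = height_m, noise_sd = 0.03,
               tilt_axis = "pitch", tilt_sign = tilt_sign)
  }
  rbind(
    nf("standing", 0.00, 0.5, noise_sd = 0.015),
    nf("walking", 0.15, 1.8),
    nf("painting", 0.10, 1.0),
    nf("bricklaying", 0.20, 0.8),
    nf("front lifting", 0.25, 0.6),
    nf("back lifting", 0.25, 0.6),
    nf("wood planing", 0.15, 1.5, vib_freq = 12, vib_amp = 0.25),
    nf("hammering", 0.20, 2.0, vib_freq = 14, vib_amp = 0.35),
    nf("screw driving", 0.08, 1.0, vib_freq = 16, vib_amp = 0.25),
    nf("drilling", 0.08, 0.8, vib_freq = 18, vib_amp = 0.30),
    nf("vertical jump", 0.15, 1.5, jump = TRUE),
    nf("jump 0.7 m", 0.15, 1.5, jump = TRUE),
    nf("jump 0.85 m", 0.15, 1.5, jump = TRUE),
    slf("forward trip", 0.40, "pitch", +1),
    slf("backward slip", 0.35, "pitch", -1),
    slf("forward fall", 0.45, "pitch", +1),
    slf("backward fall", 0.40, "pitch", -1),
    slf("leftward fall", 0.35, "roll", -1),
    slf("rightward fall", 0.35, "roll", +1),
    slf("fall while standing", 0.30, "pitch", +1),
    slf("sitting on empty chair", 0.50, "pitch", -1),
    slf("forward fall while walking", 0.45, "pitch", +1),
    slf("backward fall while walking", 0.40, "pitch", -1),
    ffh("forward 0.5 m", 0.5, +1),
    ffh("backward 0.5 m", 0.5, -1),
    ffh("forward 0.7 m", 0.7, +1),
    ffh("backward 0.7 m", 0.7, -1),
    ffh("forward 0.85 m", 0.85, +1),
    ffh("backward 0.85 m", 0.85, -1),
    ffh("forward 2.0 m", 2.0, +1),
    ffh("backward 2.0 m", 2.0, -1))
}

# Internal: gravity direction tilted by angle deg about pitch (x-z plane)
# or roll (y-z plane). Returns 3 x n matrix of unit vectors.
tilted_gravity <- function(theta_deg, axis, sgn) {
  th <- theta_deg * pi / 180
  n <- length(th)
  g <- matrix(0, 3, n)
  if (axis == "pitch") {
    # forward pitch: specific force rotates from +z toward -x
    g[1, ] <- -sgn * sin(th)
    g[3, ] <- cos(th)
  } else {
    g[2, ] <- sgn * sin(th)
    g[3, ] <- cos(th)
  }
  g
}

#' Generate one synthetic annotated recording
#'
#' Produces a 40 Hz `imu_recording` for a known subtype with class-specific
#' morphology: non-fall activities fluctuate about 1 g (vibration subtypes
#' add a 12-18 Hz component, jump subtypes a sub-0.5 g flight dip followed by
#' a >2 g landing spike); SLF recordings show gait, then a critical phase of
#' the subtype's duration with growing trunk tilt (>30 deg by impact) and SMV
#' decaying below 0.8 g, then a >3 g impact and a quiet post-fall phase; FFH
#' recordings have a near-zero specific-force free-fall phase whose duration
#' is `free_fall_duration(height)` on the sample grid, then a >3 g impact.
#'
#' Fall recordings place the loss-of-balance instant at a fixed offset inside
#' the stride-40 window grid anchored at `active_start`, so non-overlapping
#' segmentation yields exactly one critical-phase window per fall recording.
#'
#' @param klass `"NON_FALL"`, `"SLF"` or `"FFH"`.
#' @param subtype A subtype name present in `subtypes`.
#' @param seed Integer seed; the recording is a pure function of
#'   `(klass, subtype, seed)`.
#' @param subtypes Parameter table, by default [default_subtypes()].
#' @param subject_gain Optional multiplicative gain applied to the dynamic
#'   (non-gravity) signal component, emulating between-subject movement
#'   amplitude; drawn from U(0.9, 1.1) when `NULL`.
#' @return An `imu_recording`.
#' @export
generate_recording <- function(klass, subtype, seed,
                               subtypes = default_subtypes(),
                               subject_gain = NULL) {
  row <- subtypes[subtypes$klass == klass & subtypes$subtype == subtype, ]
  if (nrow(row) != 1) {
    fs_config_error(sprintf("unknown subtype '%s' for class %s", subtype, klass))
  }
  fs <- 40
  dt <- 1 / fs
  set.seed(as.integer(seed))
  gain <- if (is.null(subject_gain)) stats::runif(1, 0.9, 1.1) else subject_gain
  lead_n <- fs          # 1 s stationary lead-in (outside active segment)
  noise <- function(n, sd_acc) {
    list(acc = matrix(stats::rnorm(3 * n, 0, sd_acc), 3, n),
         gyr = matrix(stats::rnorm(3 * n, 0, 2), 3, n))
  }
  mk <- function(acc, gyr) {
    n <- ncol(acc)
    data.frame(t = (seq_len(n) - 1) * dt,
               ax = acc[1, ], ay = acc[2, ], az = acc[3, ],
               gx = gyr[1, ], gy = gyr[2, ], gz = gyr[3, ])
  }

  if (klass == "NON_FALL") {
    active_n <- 5 * fs
    n <- lead_n + active_n + lead_n
    tt <- (seq_len(n) - 1) * dt
    acc <- rbind(0, 0, rep(1, n))
    gyr <- matrix(0, 3, n)
    idx <- lead_n + seq_len(active_n)
    ta <- tt[idx]
    phase <- stats::runif(3, 0, 2 * pi)
    amp <- row$base_amp * gain
    acc[1, idx] <- acc[1, idx] + amp * sin(2 * pi * row$base_freq * ta + phase[1])
    acc[2, idx] <- acc[2, idx] + 0.6 * amp * sin(2 * pi * row$base_freq * ta + phase[2])
    acc[3, idx] <- acc[3, idx] + 0.8 * amp * sin(2 * pi * row$base_freq * ta + phase[3])
    gyr[1, idx] <- 40 * amp * sin(2 * pi * row$base_freq * ta + phase[2])
    gyr[2, idx] <- 40 * amp * sin(2 * pi * row$base_freq * ta + phase[1])
    if (is.finite(row$vib_freq)) {
      vib <- row$vib_amp * gain
      for (k in 1:3) {
        acc[k, idx] <- acc[k, idx] + vib * c(1, 0.7, 0.9)[k] *
          sin(2 * pi * row$vib_freq * ta + phase[k])
      }
      gyr[3, idx] <- gyr[3, idx] + 30 * vib * sin(2 * pi * row$vib_freq * ta + phase[3])
    }
    if (isTRUE(row$jump)) {
      # flight dip (<0.5 g) then landing spike (>2 g), inside active segment
      j0 <- lead_n + 2 * fs + sample.int(10, 1)
      dip <- j0:(j0 + 5)
      acc[, dip] <- acc[, dip] * 0.2
      land <- j0 + 6
      acc[3, land] <- 2.6 + stats::runif(1, 0, 0.8)
      acc[3, land + 1] <- 1.8
      gyr[1, dip] <- gyr[1, dip] + 60
    }
    nz <- noise(n, row$noise_sd)
    acc <- acc + nz$acc
    gyr <- gyr + nz$gyr
    ann <- list(klass = "NON_FALL", subtype = subtype,
                active_start = tt[lead_n + 1], active_end = tt[lead_n + active_n],
                loss_of_balance_t = NA_real_, impact_t = NA_real_)
    return(imu_recording(mk(acc, gyr), ann,
                         recording_id = sprintf("%s_%s_%d", klass, gsub(" ", "-", subtype), seed),
                         subject_id = sprintf("subj%03d", seed %% 997)))
  }

  # Fall classes: pre-fall phase, critical phase, impact, post-fall phase.
  crit_s <- if (klass == "SLF") row$critical_s else free_fall_duration(row$height_m)
  crit_n <- max(2L, as.integer(round(crit_s * fs)))
  # Align loss of balance so the stride-40 grid window ending mid-phase exists:
  # offset inside the third window such that its last sample falls near the
  # middle of the critical phase.
  offset <- 40L - as.integer(ceiling(crit_n / 2))
  pre_n <- 80L + offset                      # samples from active_start to balance loss
  post_n <- as.integer(1.5 * fs)             # quiet lying phase after impact
  impact_n <- 2L
  active_n <- pre_n + crit_n + impact_n + post_n
  n <- lead_n + active_n + lead_n
  tt <- (seq_len(n) - 1) * dt
  acc <- rbind(0, 0, rep(1, n))
  gyr <- matrix(0, 3, n)

  # pre-fall gait/stance
  idx_pre <- lead_n + seq_len(pre_n)
  ta <- tt[idx_pre]
  phase <- stats::runif(3, 0, 2 * pi)
  amp <- row$base_amp * gain
  acc[1, idx_pre] <- acc[1, idx_pre] + amp * sin(2 * pi * row$base_freq * ta + phase[1])
  acc[3, idx_pre] <- acc[3, idx_pre] + 0.8 * amp * sin(2 * pi * row$base_freq * ta + phase[3])
  gyr[1, idx_pre] <- 30 * amp * sin(2 * pi * row$base_freq * ta + phase[2])

  idx_crit <- lead_n + pre_n + seq_len(crit_n)
  u <- seq_len(crit_n) / crit_n              # phase progress in (0, 1]
  if (klass == "SLF") {
    # inverted-pendulum early-time behavior: angular velocity grows from ~0
    # (constant angular acceleration), so the first critical samples still
    # resemble gait and the fall becomes detectable only as tilt accumulates
    theta_end <- 55 + stats::runif(1, 0, 15)   # > 30 deg tilt by impact
    theta <- theta_end * u^2
    mag <- 1 - 0.65 * u^2                      # SMV decays below 0.8 g
    acc[, idx_crit] <- tilted_gravity(theta, row$tilt_axis, row$tilt_sign) *
      rep(mag, each = 3)
    omega <- 2 * theta_end * u / crit_s        # d(theta)/dt in deg/s
    if (row$tilt_axis == "pitch") gyr[2, idx_crit] <- row$tilt_sign * omega
    else gyr[1, idx_crit] <- row$tilt_sign * omega
  } else {
    # near-ballistic free fall: specific force ~ 0, moderate tumbling
    acc[, idx_crit] <- 0
    tumble <- stats::runif(1, 60, 150)
    gyr[2, idx_crit] <- row$tilt_sign * tumble
    gyr[1, idx_crit] <- 0.3 * tumble * sin(2 * pi * u)
  }

  # impact spike > 3 g, then quiet post-fall lying
  idx_imp <- lead_n + pre_n + crit_n + seq_len(impact_n)
  acc[3, idx_imp[1]] <- 3.5 + stats::runif(1, 0, 2)
  acc[3, idx_imp[2]] <- 2.0
  gyr[, idx_imp] <- stats::rnorm(3 * impact_n, 0, 100)
  idx_post <- (lead_n + pre_n + crit_n + impact_n) + seq_len(post_n + lead_n)
  lie <- tilted_gravity(90, if (is.na(row$tilt_axis)) "pitch" else row$tilt_axis,
                        row$tilt_sign)
  acc[, idx_post] <- matrix(lie, 3, length(idx_post))

  sd_acc <- ifelse(seq_len(n) %in% idx_crit & klass == "FFH", 0.02, row$noise_sd)
  acc <- acc + matrix(stats::rnorm(3 * n), 3, n) * rep(sd_acc, each = 3)
  gyr <- gyr + matrix(stats::rnorm(3 * n, 0, 2), 3, n)

  lob_t <- tt[lead_n + pre_n + 1]
  impact_t <- tt[lead_n + pre_n + crit_n + 1]
  ann <- list(klass = klass, subtype = subtype,
              active_start = tt[lead_n + 1],
              active_end = tt[lead_n + active_n],
              loss_of_balance_t = lob_t, impact_t = impact_t)
  imu_recording(mk(acc, gyr), ann,
                recording_id = sprintf("%s_%s_%d", klass, gsub(" ", "-", subtype), seed),
                subject_id = sprintf("subj%03d", seed %% 997))
}

#' Build a generator specification
#'
#' Default class counts reproduce the study's 5991:1630:729 imbalance scaled
#' by `scale`, spread round-robin over the subtypes of each class.
#'
#' @param counts Optional data frame with columns `klass`, `subtype`, `n`;
#'   overrides the scaled defaults.
#' @param class_totals Optional named vector of per-class recording totals
#'   (spread round-robin over each class's subtypes); overrides `scale`.
#' @param scale Scaling factor applied to the 5991/1630/729 class totals.
#' @param seed Master seed; per-recording sub-seeds are derived by a
#'   counter-based rule so earlier recordings are unaffected by later spec
#'   changes.
#' @param subtypes Subtype parameter table.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(counts = NULL, class_totals = NULL, scale = 0.1,
                           seed = 1, subtypes = default_subtypes()) {
  if (is.null(counts)) {
    if (is.null(class_totals)) {
      class_totals <- round(c(NON_FALL = 5991, SLF = 1630, FFH = 729) * scale)
    }
    counts <- do.call(rbind, lapply(CLASSES, function(kl) {
      st <- subtypes$subtype[subtypes$klass == kl]
      total <- class_totals[[kl]]
      base <- rep(total %/% length(st), length(st))
      extra <- total %% length(st)
      if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1
      data.frame(klass = kl, subtype = st, n = base)
    }))
  }
  if (any(counts$n < 0)) fs_config_error("counts must be non-negative")
  bad <- !paste(counts$klass, counts$subtype) %in%
    paste(subtypes$klass, subtypes$subtype)
  if (any(bad)) {
    fs_config_error(sprintf("unknown subtype(s): %s",
                            paste(counts$subtype[bad], collapse = ", ")))
  }
  structure(list(counts = counts, seed = as.integer(seed),
                 sample_rate_hz = 40, subtypes = subtypes),
            class = "generator_spec")
}

#' Generate a dataset of annotated recordings
#'
#' Deterministic under the spec's master seed: recording `i` uses sub-seed
#' `derive(seed, i)`, so the same spec and seed always reproduce bitwise
#' identical recordings.
#'
#' @param spec A [generator_spec()].
#' @return List of `imu_recording` objects, ordered NON_FALL, SLF, FFH.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  counts <- spec$counts
  counts$klass <- factor(counts$klass, levels = CLASSES)
  counts <- counts[order(counts$klass), ]
  out <- vector("list", sum(counts$n))
  counter <- 0L
  pos <- 0L
  for (r in seq_len(nrow(counts))) {
    for (i in seq_len(counts$n[r])) {
      counter <- counter + 1L
      pos <- pos + 1L
      out[[pos]] <- generate_recording(as.character(counts$klass[r]),
                                       counts$subtype[r],
                                       seed = derive_seed(spec$seed, counter),
                                       subtypes = spec$subtypes)
    }
  }
  out
}
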