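# Annotated IMU recording container and delimited-text I/O.
#
# One recording = one CSV file: `# key=value` metadata header lines followed
# by a `t,ax,ay,az,gx,gy,gz` sample table. Units are fixed at the I/O
# boundary: specific force in g (sensor full scale +/- 16 g), angular rate in
# deg/s (+/- 2000 deg/s), timestamps on an exact 1/40 s grid.

ACCEL_FULL_SCALE_G <- 16
GYRO_FULL_SCALE_DPS <- 2000
SAMPLE_COLUMNS <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
TIME_TOL_S <- 1e-6

#' Construct an annotated IMU recording
#'
#' Bundles a regularly sampled 40 Hz sensor stream with its event annotation.
#' The constructor validates the object and raises a classed error on the
#' first violation; use [validate_recording()] to obtain the full list.
#'
#' @param samples Data frame with columns `t, ax, ay, az, gx, gy, gz`:
#'   time in seconds (exact multiples of `1/sample_rate_hz`), specific force
#'   in g, angular rate in deg/s.
#' @param annotation Named list with `klass` (one of `"NON_FALL"`, `"SLF"`,
#'   `"FFH"`), `subtype` (free text), `active_start`, `active_end` (seconds),
#'   and for fall classes `loss_of_balance_t` and `impact_t` (seconds).
#' @param recording_id,subject_id Identifiers.
#' @param sample_rate_hz Sampling rate; fixed at 40 Hz in this framework.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(samples, annotation, recording_id = "rec",
                          subject_id = "subj", sample_rate_hz = 40) {
  rec <- structure(
    list(recording_id = as.character(recording_id),
         subject_id = as.character(subject_id),
         sample_rate_hz = as.numeric(sample_rate_hz),
         samples = as.data.frame(samples),
         annotation = annotation),
    class = "imu_recording")
  v <- validate_recording(rec)
  if (length(v)) {
    first <- v[[1]]
    switch(attr(v, "kinds")[[1]],
           format = fs_format_error(first),
           integrity = fs_integrity_error(first),
           annotation = fs_annotation_error(first),
           fs_validation_error(first))
  }
  rec
}

#' @export
print.imu_recording <- function(x, ...) {
  ann <- x$annotation
  cat(sprintf("<imu_recording> %s (%s / %s), %d samples @ %g Hz\n",
              x$recording_id, ann$klass, ann$subtype,
              nrow(x$samples), x$sample_rate_hz))
  cat(sprintf("  active [%.3f, %.3f] s", ann$active_start, ann$active_end))
  if (!is.null(ann$loss_of_balance_t) && !is.na(ann$loss_of_balance_t)) {
    cat(sprintf("; critical [%.3f, %.3f] s", ann$loss_of_balance_t, ann$impact_t))
  }
  cat("\n")
  invisible(x)
}

#' Validate an IMU recording
#'
#' Pure check of every container invariant: sample-column presence and
#' finiteness, sensor full-scale bounds, exact 1/40 s timestamp grid,
#' annotation consistency (fall-phase ordering, presence rules per class)
#' and a minimum of 40 in-segment samples. Reports, never raises.
#'
#' @param rec An `imu_recording` (or a bare list with the same fields).
#' @return Character vector of violation messages, ordered deterministically
#'   (sample-level issues by index, then annotation issues). Empty when valid.
#' @export
validate_recording <- function(rec) {
  msgs <- character(); kinds <- character()
  add <- function(msg, kind) {
    msgs <<- c(msgs, msg); kinds <<- c(kinds, kind)
  }
  s <- rec$samples
  ann <- rec$annotation
  missing_cols <- setdiff(SAMPLE_COLUMNS, names(s))
  if (length(missing_cols)) {
    add(sprintf("missing sample column(s): %s", paste(missing_cols, collapse = ", ")),
        "format")
    out <- msgs; attr(out, "kinds") <- kinds
    return(out)
  }
  if (nrow(s) == 0) {
    add("recording contains no samples", "validation")
  } else {
    bad_finite <- which(!stats::complete.cases(s) |
                          rowSums(!is.finite(as.matrix(s))) > 0)
    for (i in bad_finite) {
      add(sprintf("non-finite sample value at index %d", i), "validation")
    }
    dt <- 1 / rec$sample_rate_hz
    if (nrow(s) > 1) {
      gaps <- which(abs(diff(s$t) - dt) > TIME_TOL_S)
      if (length(gaps)) {
        add(sprintf("timestamp grid violated at index %d: step %.6f s (expected %.6f s)",
                    gaps[1] + 1, diff(s$t)[gaps[1]], dt), "integrity")
      }
    }
    off_grid <- which(abs(s$t / dt - round(s$t / dt)) > TIME_TOL_S * rec$sample_rate_hz)
    if (length(off_grid)) {
      add(sprintf("timestamp not a multiple of 1/%g s at index %d",
                  rec$sample_rate_hz, off_grid[1]), "integrity")
    }
    for (ax in c("ax", "ay", "az")) {
      bad <- which(abs(s[[ax]]) > ACCEL_FULL_SCALE_G)
      for (i in bad) add(sprintf("accelerometer full-scale bound (+/-%d g) exceeded: %s = %.3f at index %d",
                                 ACCEL_FULL_SCALE_G, ax, s[[ax]][i], i), "validation")
    }
    for (gx in c("gx", "gy", "gz")) {
      bad <- which(abs(s[[gx]]) > GYRO_FULL_SCALE_DPS)
      for (i in bad) add(sprintf("gyroscope full-scale bound (+/-%d deg/s) exceeded: %s = %.1f at index %d",
                                 GYRO_FULL_SCALE_DPS, gx, s[[gx]][i], i), "validation")
    }
  }
  if (is.null(ann$klass) || !ann$klass %in% CLASSES) {
    add(sprintf("annotation klass must be one of %s", paste(CLASSES, collapse = "/")),
        "annotation")
  } else {
    has_lob <- !is.null(ann$loss_of_balance_t) && !is.na(ann$loss_of_balance_t)
    has_imp <- !is.null(ann$impact_t) && !is.na(ann$impact_t)
    if (ann$klass == "NON_FALL") {
      if (has_lob) add("NON_FALL annotation must not carry loss_of_balance_t", "annotation")
      if (has_imp) add("NON_FALL annotation must not carry impact_t", "annotation")
    } else {
      if (!has_lob) add(sprintf("%s annotation requires loss_of_balance_t", ann$klass), "annotation")
      if (!has_imp) add(sprintf("%s annotation requires impact_t", ann$klass), "annotation")
      if (has_lob && has_imp) {
        if (!(ann$impact_t > ann$loss_of_balance_t)) {
          add("annotation requires loss_of_balance_t < impact_t (critical phase must have positive duration)",
              "annotation")
        }
        if (ann$active_start > ann$loss_of_balance_t || ann$impact_t > ann$active_end) {
          add("annotation requires active_start <= loss_of_balance_t < impact_t <= active_end",
              "annotation")
        }
      }
    }
    if (nrow(s) > 0 && !is.null(ann$active_start) && !is.null(ann$active_end)) {
      n_in <- sum(s$t >= ann$active_start - TIME_TOL_S & s$t <= ann$active_end + TIME_TOL_S)
      if (n_in < 40) {
        add(sprintf("active segment holds %d samples; at least one full 40-sample window required", n_in),
            "annotation")
      }
    }
  }
  out <- msgs
  attr(out, "kinds") <- kinds
  out
}

ANNOTATION_KEYS <- c("recording_id", "subject_id", "sample_rate_hz", "klass",
                     "subtype", "active_start", "active_end",
                     "loss_of_balance_t", "impact_t")

#' Write an IMU recording to a self-describing CSV file
#'
#' Metadata is stored as `# key=value` header lines, samples as CSV rows.
#' Numeric fields are written with 17 significant digits so that
#' [read_recording()] reproduces them bit-identically.
#'
#' @param rec A valid `imu_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  v <- validate_recording(rec)
  if (length(v)) fs_validation_error(paste0("refusing to write invalid recording: ", v[[1]]))
  ann <- rec$annotation
  num <- function(x) {
    if (is.null(x) || is.na(x)) "NA" else sprintf("%.17g", as.numeric(x))
  }
  header <- c(
    paste0("# recording_id=", rec$recording_id),
    paste0("# subject_id=", rec$subject_id),
    paste0("# sample_rate_hz=", num(rec$sample_rate_hz)),
    paste0("# klass=", ann$klass),
    paste0("# subtype=", ann$subtype),
    paste0("# active_start=", num(ann$active_start)),
    paste0("# active_end=", num(ann$active_end)),
    paste0("# loss_of_balance_t=", num(ann$loss_of_balance_t)),
    paste0("# impact_t=", num(ann$impact_t)))
  s <- rec$samples[, SAMPLE_COLUMNS]
  body <- do.call(paste, c(lapply(s, function(col) sprintf("%.17g", col)), sep = ","))
  con <- tryCatch(file(path, "w"), error = function(e) {
    fs_error(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
             "fallsense_io_error")
  })
  on.exit(close(con))
  writeLines(c(header, paste(SAMPLE_COLUMNS, collapse = ","), body), con)
  invisible(path)
}

#' Read an IMU recording from its CSV form
#'
#' Parses the `# key=value` metadata header and the sample table written by
#' [write_recording()], then validates every container invariant.
#'
#' @param path Path to a recording file.
#' @return A validated `imu_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) {
    fs_error(sprintf("recording file '%s' does not exist", path), "fallsense_io_error")
  }
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    key <- substr(kv, 1, eq - 1)
    meta[[key]] <- substr(kv, eq + 1, nchar(kv))
  }
  missing_keys <- setdiff(c("klass", "subtype", "active_start", "active_end"), names(meta))
  if (length(missing_keys)) {
    fs_format_error(sprintf("metadata header missing key(s): %s",
                            paste(missing_keys, collapse = ", ")))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 1) fs_format_error("no sample table found")
  cols <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  missing_cols <- setdiff(SAMPLE_COLUMNS, cols)
  if (length(missing_cols)) {
    fs_format_error(sprintf("missing sample column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  samples <- utils::read.csv(text = paste(body, collapse = "\n"))
  samples <- samples[, SAMPLE_COLUMNS]
  num_or_na <- function(key) {
    val <- meta[[key]]
    if (is.null(val) || val == "NA") NA_real_ else as.numeric(val)
  }
  ann <- list(klass = meta$klass, subtype = meta$subtype,
              active_start = num_or_na("active_start"),
              active_end = num_or_na("active_end"),
              loss_of_balance_t = num_or_na("loss_of_balance_t"),
              impact_t = num_or_na("impact_t"))
  imu_recording(samples, ann,
                recording_id = if (is.null(meta$recording_id)) "rec" else meta$recording_id,
                subject_id = if (is.null(meta$subject_id)) "subj" else meta$subject_id,
                sample_rate_hz = if (is.null(meta$sample_rate_hz)) 40 else as.numeric(meta$sample_rate_hz))
}
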