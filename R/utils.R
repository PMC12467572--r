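# Internal helpers shared across modules.

CLASSES <- c("NON_FALL", "SLF", "FFH")

fs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fallsense_error")))
}

fs_format_error     <- function(msg) fs_error(msg, "fallsense_format_error")
fs_integrity_error  <- function(msg) fs_error(msg, "fallsense_integrity_error")
fs_annotation_error <- function(msg) fs_error(msg, "fallsense_annotation_error")
fs_validation_error <- function(msg) fs_error(msg, "fallsense_validation_error")
fs_parameter_error  <- function(msg) fs_error(msg, "fallsense_parameter_error")
fs_domain_error     <- function(msg) fs_error(msg, "fallsense_domain_error")
fs_config_error     <- function(msg) fs_error(msg, "fallsense_config_error")
fs_registry_error   <- function(msg) fs_error(msg, "fallsense_registry_error")
fs_environment_error <- function(msg) fs_error(msg, "fallsense_environment_error")
fs_stratification_error <- function(msg) fs_error(msg, "fallsense_stratification_error")

#' @noRd
as_class_factor <- function(x) factor(as.character(x), levels = CLASSES)

# Counter-based seed splitting: the i-th derived seed depends only on the
# master seed and the counter, never on how many draws preceded it, so
# extending a dataset spec leaves earlier recordings untouched.
derive_seed <- function(master_seed, counter) {
  master <- as.numeric(master_seed) %% 65536
  as.integer((master * 32768 + as.numeric(counter)) %% 2147483647)
}

# Column-wise moments of a (len x n) matrix without apply() overhead.
col_min <- function(m) do.call(pmin, asplit(m, 1))
col_max <- function(m) do.call(pmax, asplit(m, 1))

# Largest-remainder apportionment of round(total_i * fraction) so that
# the rounded per-class counts sum to round(sum * fraction).
largest_remainder <- function(counts, fraction) {
  raw <- counts * fraction
  base <- floor(raw)
  want <- round(sum(counts) * fraction)
  rem <- raw - base
  extra <- want - sum(base)
  if (extra > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  } else if (extra < 0) {
    ord <- order(rem, decreasing = FALSE)
    take <- ord[seq_len(-extra)]
    base[take] <- base[take] - 1
  }
  as.integer(base)
}
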