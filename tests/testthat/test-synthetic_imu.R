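test_that("free-fall duration follows sqrt(2h/g)", {
  expect_equal(free_fall_duration(2.0), 0.6386, tolerance = 1e-4)
  expect_equal(free_fall_duration(0.5), 0.3193, tolerance = 1e-4)
  expect_error(free_fall_duration(0), class = "fallsense_domain_error")
  expect_error(free_fall_duration(-1), class = "fallsense_domain_error")
})

test_that("FFH critical phase matches ballistic duration on the sample grid", {
  heights <- c("forward 0.5 m" = 0.5, "forward 0.7 m" = 0.7,
               "forward 0.85 m" = 0.85, "forward 2.0 m" = 2.0)
  for (nm in names(heights)) {
    h <- heights[[nm]]
    rec <- generate_recording("FFH", nm, seed = 11)
    d <- rec$annotation$impact_t - rec$annotation$loss_of_balance_t
    expect_lte(abs(d - free_fall_duration(h)), 1 / 40 + 1e-9)
    # SMV stays below 0.2 g throughout free fall
    s <- rec$samples
    crit <- s$t >= rec$annotation$loss_of_balance_t &
      s$t < rec$annotation$impact_t - 1e-9
    expect_lt(max(compute_smv(s[crit, ])), 0.2)
    # impact spike follows
    post <- s$t >= rec$annotation$impact_t & s$t < rec$annotation$impact_t + 0.05
    expect_gt(max(compute_smv(s[post, ])), 3)
  }
})

test_that("non-fall morphology contracts hold", {
  # stationary: SMV within 1 g +/- 0.1 g at every sample, several seeds
  for (seed in c(1, 9, 77)) {
    rec <- generate_recording("NON_FALL", "standing", seed = seed)
    expect_true(all(abs(compute_smv(rec$samples) - 1) <= 0.1))
    expect_true(is.na(rec$annotation$loss_of_balance_t))
  }
  # jump: sub-0.5 g flight dip then >2 g landing spike inside the active part
  rec <- generate_recording("NON_FALL", "vertical jump", seed = 4)
  s <- rec$samples
  act <- s$t >= rec$annotation$active_start & s$t <= rec$annotation$active_end
  smv <- compute_smv(s[act, ])
  expect_lt(min(smv), 0.5)
  expect_gt(max(smv), 2)
  # vibration subtype carries 12-18 Hz power
  drill <- generate_recording("NON_FALL", "drilling", seed = 4)
  expect_gt(stats::sd(compute_smv(drill$samples[81:240, ])), 0.05)
})

test_that("SLF critical phase echoes its configured duration and tilts", {
  rec <- generate_recording("SLF", "forward trip", seed = 7)
  ann <- rec$annotation
  expect_equal(ann$impact_t - ann$loss_of_balance_t, 0.40, tolerance = 1 / 40)
  s <- rec$samples
  crit <- which(s$t >= ann$loss_of_balance_t & s$t < ann$impact_t - 1e-9)
  last <- utils::tail(crit, 3)
  pitch <- atan2(-s$ax[last], sqrt(s$ay[last]^2 + s$az[last]^2)) * 180 / pi
  expect_gt(max(abs(pitch)), 30)            # tilt drift > 30 deg by impact
  expect_lt(min(compute_smv(s[crit, ])), 0.8)  # SMV decays below 0.8 g
})

test_that("generate_recording rejects unknown subtypes", {
  expect_error(generate_recording("SLF", "moonwalk", seed = 1),
               class = "fallsense_config_error")
})

test_that("dataset generation is deterministic, seed-sensitive and count-exact", {
  spec <- generator_spec(class_totals = c(NON_FALL = 6, SLF = 4, FFH = 3), seed = 5)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_length(d1, 13)
  kl <- vapply(d1, function(r) r$annotation$klass, "")
  expect_equal(as.vector(table(factor(kl, levels = c("NON_FALL", "SLF", "FFH")))),
               c(6, 4, 3))
  expect_identical(lapply(d1, `[[`, "samples"), lapply(d2, `[[`, "samples"))
  d3 <- generate_dataset(generator_spec(class_totals = c(NON_FALL = 6, SLF = 4, FFH = 3),
                                        seed = 6))
  expect_false(identical(d1[[1]]$samples, d3[[1]]$samples))
})

test_that("default spec reproduces the 5991:1630:729 imbalance under scaling", {
  spec <- generator_spec(scale = 0.01, seed = 1)
  counts <- tapply(spec$counts$n, factor(spec$counts$klass,
                                         levels = c("NON_FALL", "SLF", "FFH")), sum)
  expect_equal(as.vector(counts), round(c(5991, 1630, 729) * 0.01))
})

test_that("classes are separable by construction at the SMV level", {
  mean_crit_smv <- function(rec) {
    s <- rec$samples; ann <- rec$annotation
    if (ann$klass == "NON_FALL") {
      idx <- s$t >= ann$active_start & s$t <= ann$active_end
    } else {
      idx <- s$t >= ann$loss_of_balance_t & s$t < ann$impact_t - 1e-9
    }
    mean(compute_smv(s[idx, ]))
  }
  spec <- generator_spec(class_totals = c(NON_FALL = 30, SLF = 30, FFH = 30), seed = 9)
  recs <- generate_dataset(spec)
  kl <- vapply(recs, function(r) r$annotation$klass, "")
  m <- tapply(vapply(recs, mean_crit_smv, 0), kl, mean)
  expect_lt(m[["FFH"]], m[["SLF"]])
  expect_lt(m[["SLF"]], m[["NON_FALL"]])
})
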