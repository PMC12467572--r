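---
title: "Methods: pre-impact fall detection from a single waist-mounted IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-impact fall detection from a single waist-mounted IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A wearable airbag can prevent fall injuries only if the fall is recognized
*before* impact — with enough lead time to cover the ~130 ms inflation of
the bag. Detection must work for two very different fall families: a
**same-level fall (SLF)**, whose critical phase (balance loss to impact)
lasts only ~0.3–0.5 s and looks like a growing trunk tilt, and a
**fall-from-height (FFH)**, whose critical phase is dominated by free fall —
near-zero specific force for `sqrt(2h/g)` seconds. The hard part is the
negative class: occupational activity includes 12–18 Hz tool vibration and
deliberate jumps whose accelerometer signatures overlap with falls.

`fallsense` implements the full detection pipeline on 40 Hz tri-axial
accelerometer (±16 g) and gyroscope (±2000 °/s) streams, and ships a
synthetic recording generator so that every stage is testable end to end.

# The synthetic signal model

The generator (`generate_recording()`, `generate_dataset()`) emulates class
morphology at the level the downstream pipeline consumes — windowed SMV,
orientation and cross-axis statistics — and deliberately not full human
biomechanics.

* **Non-fall activities** (13 subtypes) fluctuate about 1 g with
  subtype-specific low-frequency movement; vibration subtypes (wood planing,
  hammering, screw driving, drilling) add a 12–18 Hz sinusoid; jump subtypes
  insert a sub-0.5 g flight dip followed by a >2 g landing spike.
* **SLF critical phases** use inverted-pendulum early-time kinematics:
  tilt angle `θ(u) = θ_end u²` (constant angular acceleration, so angular
  velocity starts near zero and the first critical samples still resemble
  gait), θ_end drawn from 55–70°, and specific-force magnitude decaying as
  `1 − 0.65 u²` (below 0.8 g before impact). Critical durations per subtype
  lie in 0.30–0.50 s.
* **FFH critical phases** have near-zero specific force for exactly
  `sqrt(2h/9.81)` seconds rounded to the 40 Hz grid (drop heights 0.5, 0.7,
  0.85 and 2.0 m, forward/backward), moderate tumbling rates, then a >3 g
  impact spike and a quiet lying phase.

Noise is additive Gaussian per channel: σ = 0.03 g (accelerometer) and
2 °/s (gyroscope). Two deviations from a naive reading are deliberate:
the stationary subtype uses σ = 0.015 g and free-fall segments use
σ = 0.02 g, so the contracts "standing SMV within 1 ± 0.1 g at every
sample" and "free-fall SMV < 0.2 g" hold at any seed with >5σ margin.
A subject-level gain drawn from U(0.9, 1.1) multiplies the *dynamic*
(non-gravity) component only: accelerometers are factory-calibrated, so
between-subject variability belongs to movement amplitude, not to the
gravity reference — and a gain on gravity itself would break the standing
contract by construction.

Fall recordings place the loss-of-balance instant at a fixed offset inside
the stride-40 window grid anchored at `active_start`, so that
non-overlapping segmentation yields exactly one critical-phase window per
fall recording (its last sample sits near the middle of the critical
phase). This makes window-level class counts a deterministic function of
recording counts.

Seeds are split counter-based: recording *i* of a dataset uses a sub-seed
that depends only on the master seed and *i*, so enlarging a dataset spec
never reshuffles earlier recordings. The default spec reproduces the
5991:1630:729 class imbalance under any scale factor.

**What passing tests on this data do and do not show.** The generator is
separable by construction (mean critical-phase SMV: FFH ≪ SLF < non-fall),
so near-perfect cross-validated scores demonstrate that the pipeline is
implemented correctly — windowing, labeling, weighting, selection and
evaluation compose without leakage — not that the method would reach any
particular accuracy on real recordings, which carry inter-subject
variability, sensor artifacts and much richer activity overlap.

# Windowing, labeling and augmentation

Windows are fixed at **40 samples** (1 s). A moving median filter
(`median_filter()`) with **kernel 5** (125 ms) and reflection padding
denoises each window; the kernel is a package default — 5 samples removes
single-sample spikes while preserving the sub-20 Hz band of human motion.
The training stride is **40** (non-overlapping) to avoid near-duplicate
windows leaking across splits; detection replay uses stride 1.

A window from a fall recording is labeled with the fall class iff its
**last sample time** lies in the half-open critical phase
`[loss_of_balance_t, impact_t)`; windows ending at/after impact (post-fall
phase) are discarded. Keying on the last sample rather than full
containment is necessary because SLF critical phases (~0.4 s) are shorter
than the 1 s window; it also makes the lead-time convention (below)
coherent: a window's prediction becomes available at its last sample.

Augmentation (`augment_windows()`) emits three copies per training window —
jitter, scaling, temporal warping — at intensity level L in 1..4: jitter
σ = 0.01·L g (accelerometer) and L °/s (gyroscope); one scaling factor
from U(1 − 0.05 L, 1 + 0.05 L); warping via a monotone (Hyman) cubic time
map with 4 interior knots displaced by N(0, 0.05 L) of the window duration,
cubically resampled back to 40 samples. The magnitudes are package
defaults. Augmented windows are confined to the training side of every
split, and inside cross-validation augmentation is re-applied per fold to
the fold's training portion only — applying it once before CV would leak
transformed copies of test windows into training.

# Two-stage features: why 168

Stage 1 expands each 40×6 window into 24 per-time-step channels: the 6 raw
axes; per sensor the L2 norm (SMV), L1 magnitude (SMA), and cross-axis
min/mean/max/range/std/var at each time step; plus gravity-referenced
`roll = atan2(ay, az)` and `pitch = atan2(−ax, sqrt(ay² + az²))` from the
accelerometer only (a gyroscope has no gravity reference, which is what
fixes the 10 + 8 + 6 channel accounting). Stage 2 summarizes every channel
with 7 statistics — min, mean, max, variance, standard deviation,
Fisher–Pearson skewness `m3/m2^1.5` and excess kurtosis `m4/m2² − 3` —
giving 24 × 7 = **168** named features (`<channel>__<stat>`), a frozen
registry that all selection output refers to by name.

Numerical conventions: population moments throughout (divide by 3 across
axes, by 40 across the window); `atan2(0, 0) := 0` so free-fall windows
stay finite; skewness/kurtosis defined as 0 when `m2 < 1e−12`. Note the
whole vector is invariant to a permutation of the 40 samples — within-window
temporal *order* enters only through the stage-1 channel construction, not
stage 2 — a known representational limit of the design.

# Ensemble feature selection

Two selectors run on a held-out validation split of the training data and
their union is the definitive set (`ensemble_select()`).

**SHAP-Select** (`shap_select()`): exact tree-path SHAP contributions
φ_ijk of the fitted booster (deterministic, no sampling) enter a
multinomial regression with the true label as response and linear predictor
`η_ik = bias_ik + Σ_j β_j φ_ijk` — one shared coefficient per feature (J
coefficients total; the booster's bias contribution is a fixed offset, so
β ≡ 1 recovers the model's own margins). The fit maximizes a
ridge-penalized likelihood (ridge 1e−6) by BFGS with analytic gradient;
Wald p-values come from the penalized observed information. The Bonferroni
divisor is **J** (one test per feature), and `mode = "significant"` keeps
{β_j > 0, p_j < α/J} while `mode = "nonnegative"` keeps everything not
significantly negative.

When the booster separates the validation set (mean deviance per
observation < 0.02), the maximum-likelihood estimate diverges and the
observed information degenerates — Wald standard errors explode and no
feature can reach significance, the multinomial analogue of
quasi-complete separation. The regression then refits with a stabilizing
ridge scaled to the sample size (0.05 per observation), which keeps the
fit off the boundary and restores informative curvature; the refit is
flagged in the diagnostics (`ridge_fallback`). On noisy, realistic data
the 1e−6 ridge is the one that applies.

**Permutation feature importance** (`permutation_importance()`): baseline
macro-F1 on the validation set, then R = 10 independent within-column
permutations per feature; importance is the mean drop, and a feature is
retained iff the mean drop is strictly positive. Permuting a constant
column is the identity, so its drop is exactly 0.

The union inherits the complementary strengths argued for this design:
statistical consistency from the SHAP route, direct empirical impact from
the permutation route, with each compensating the other's blind spot
(class imbalance and collinearity respectively).

# Weighted training and Bayesian optimization

Sample weights follow the inverse-frequency rule `w_i = N / (K n_c(i))`,
which gives every class equal total weight and satisfies `Σ w_i = N`
exactly. Boosting uses a softmax objective over K = 3 classes with a fixed
iteration count (no early stopping) and single-threaded, seeded fits for
reproducibility. Ties in predicted scores break to the lowest class index.

The search spaces (`search_space()`) encode the published ranges per
backend — learning rate log-uniform [0.005, 0.30], iterations [100, 800],
depth [3, 10], row subsample [0.50, 1.00], column sample [0.30, 1.00],
minimum loss reduction [0, 5], minimum child weight (integer [1, 10] for
XGBoost, log-uniform [1e−3, 10] for LightGBM), leaves [15, 255]
(LightGBM), bagging temperature [0, 1] and L2 leaf regularization
log-uniform [1e−3, 10] (CatBoost), L1/L2 log-uniform [1e−6, 10] — and the
published per-backend optima ship as `paper_optimum()` presets. Model
fitting is implemented on the XGBoost backend; the LightGBM and CatBoost
spaces and presets are defined as data and requesting those backends
raises an informative error, keeping the three-backend contract explicit
for evaluation code, which is backend-blind.

`bayes_optimize()` is a sequential model-based optimizer: a Latin-hypercube
initial design (up to 8 points), then a Gaussian-process surrogate (RBF
kernel, fixed length-scale `0.3√d`, small nugget) over the unit cube with
expected-improvement proposals drawn from a 500-point random candidate
pool. Each trial fits a weighted booster on an inner stratified 80/20
split and scores macro-F1 on the inner validation part. The budget,
acquisition and split protocol are package choices (the study design names
only "Bayesian optimization maximizing validation macro-F1"); everything
is deterministic under the seed. For large training sets the trials run on
a stratified subsample (default cap 1500 rows) — a tuning-time control
that leaves the final fits on the full data.

# Evaluation

Macro metrics average one-vs-rest per-class quantities with equal class
weight: accuracy, sensitivity, specificity, F1 `2TP/(2TP+FP+FN)` and MCC.
A per-class term with a zero denominator (possible in degenerate folds)
contributes 0 to its average — the printed formulas do not address this
case, so the guard is documented here. PR-AUC is average precision (step
integration, no trapezoidal interpolation), the conservative choice under
class imbalance; a class absent from the truth is reported as missing, not
0. Cross-validation is stratified (each fold within one window of the
global class proportions) with seeded, logged fold assignment, reported as
mean ± sd over folds.

**Lead time** is `(impact_t − detection window end) · 1000` ms, measured by
replaying stride-1 windows over a recording and firing on the first
fall-labeled prediction (a consecutive-window vote is configurable,
default 1 — the trigger rule is a package choice). Detection at or after
impact counts as a missed detection, excluded from lead-time means and
tallied separately. Under this convention FFH lead times exceed SLF lead
times on the default synthetic data: free fall is distinctive within a few
samples, whereas a same-level fall must first accumulate tilt. Scoring
latency per window is wall-clock, reported with host metadata only, and
deliberately excluded from the reproducibility manifest.

`compare_models()` runs one-way ANOVA on fold-level metric values across
models, then Tukey HSD at α = 0.05, and renders a grouping string such as
`"(1),(2) > (3)"`; with identical values everywhere it reports F = 0 and
no significant pairs rather than 0/0.

# The demo pipeline and problem sizes

`pipeline_config()` gathers every default in one place. The demo
configuration simulates 600/160/72 recordings (the study's imbalance at
~1/10 scale), yielding ~3700 windows, runs 25 optimization trials, selects
with the significant-SHAP mode plus 5 permutation repeats, and evaluates
with 5-fold CV and a 20-recording-per-class lead-time replay. These sizes
keep a full run in the low minutes on a single core while leaving every
class with enough windows for stratified 5-fold CV. `run_pipeline()`
persists each stage's artifact and a manifest of MD5 checksums; a rerun
with the same config and seed reproduces the checksums bit for bit.

# Known limitations

* The generator's separability means synthetic benchmarks bound
  implementation correctness, not field accuracy.
* Feature selection on near-separable validation data retains very few
  features (permutation drops are mostly exactly 0 when the baseline is
  perfect); on realistic data the retained sets are much larger. The
  ensemble-union safeguard is exercised by the planted-signal tests rather
  than by the saturated demo data.
* Stage-2 statistics are order-invariant within the window; rhythm
  information enters only via stage-1 channel dynamics.
* Only the XGBoost backend is fittable; LightGBM/CatBoost comparisons
  require their own implementations of the same contract.
* The lead-time convention (window end, first-fire, vote = 1) is one of
  several defensible readings; alternatives shift reported leads by a few
  sample periods.
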