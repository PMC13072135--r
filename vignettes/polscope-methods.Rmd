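---
title: "Methods: simulating and testing the metabolism-boldness link in zebrafish"
author: "polscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and testing the metabolism-boldness link in zebrafish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polscope)
```

## The scientific problem

The pace-of-life syndrome (POLS) hypothesis predicts that individuals
with higher baseline metabolic demands take more risks to secure
resources. In adult zebrafish this is tested by relating **routine
metabolic rate** (RMR) — mass-normalized oxygen consumption of a
spontaneously swimming fish in a sealed chamber — to **boldness** in
the novel tank test (NTT): bold fish swim higher in the water column
and explore more of an unfamiliar tank.

`polscope` implements that entire analysis chain as tested code, plus a
cohort simulator with known ground truth, so every stage — the
respirometry arithmetic, the trajectory metrics, the composite boldness
index, and the statistical battery — can be validated and power-checked
without access to any animal data.

## The measurement model

### Closed-chamber respirometry

A session records dissolved O~2~ (mg/l) at the start (t1) and end (t2)
of a 30-min trial in the fish chamber and in a parallel fish-free
*blank* chamber. Consumption is the blank-corrected drop

$$[\mathrm{O_2}]_{consumed} =
  ([\mathrm{O_2}]_{f,t1} - [\mathrm{O_2}]_{f,t2}) -
  ([\mathrm{O_2}]_{b,t1} - [\mathrm{O_2}]_{b,t2}),$$

so drift common to both chambers (degassing, temperature) cancels
identically; `compute_o2_consumed()` is exactly this expression and is
linear in the four readings with coefficients (+1, −1, −1, +1). RMR is
consumption divided by body mass, reported **per trial** (mg O~2~/l/g
per 30 min) with no per-hour rescaling, because the concentration-based
unit is the convention for this assay; the trial duration is carried in
every record so rescaling is a trivial downstream transform. Chamber
volume (500 ml on both sides) never enters the concentration
arithmetic; an absolute-mg variant would be `consumed * volume` and is
deliberately not the default.

QC excludes records with consumption ≤ 0. A live fish must consume
oxygen over 30 min, so non-positive values indicate data-entry or meter
error; zero is grouped with the negatives because it is equally
impossible physiologically. Records with a missing blank reading are
invalid — the blank correction is the core of the method, so no
imputation is attempted. The data model carries one blank pair per
record, which also accommodates batch-shared blanks by repetition.

### Novel-tank behavioral metrics

Six measures are extracted from a uniformly sampled 3D trajectory of a
single tracked body point inside a 15 × 15 × 15 cm tank:

* **bottom distance** — time-mean height above the floor (cm);
* **center distance** — time-mean horizontal distance from the tank's
  central vertical axis (cm). The horizontal-plane convention matches
  the thigmotaxis reading of this measure; a 3D-center variant is
  available via `mean_center_distance(use_3d = TRUE)` for sensitivity
  analysis;
* **distance traveled** — summed frame-to-frame displacement (cm);
* **percent explored** — the tank is partitioned into 10 × 10 × 10 =
  1000 axis-aligned voxels (the cube-root factorization is the natural
  reading of "1000 voxels" for a cubic tank); a voxel counts once it
  holds at least one frame. Cells are half-open per axis with the far
  wall folded into the last cell, so positions exactly on the boundary
  are countable;
* **percent immobile** — fraction of inter-frame speeds strictly below
  a cut-off (default 1.5 mm/s). Strict `<` is the natural reading of a
  cut-off *for* immobility; the choice is immaterial for continuous
  data but fixed for testability;
* **maximum velocity** — the median of the `ceiling(0.05 n)` largest
  speeds. The ceiling rule guarantees a non-empty subset and a
  deterministic value; at least 20 samples are required so "top 5%" is
  meaningful.

Speeds are raw frame-to-frame displacements divided by the frame
interval, unsmoothed: smoothing would shift the break in the speed
distribution that motivates the immobility cut-off.
`detect_immobility_threshold()` reconstructs that break as the deepest
valley of a kernel-smoothed histogram of log~10~ speed between the two
dominant modes; the mode and valley must be substantive (peaks at
least 10% of the maximum density, valley at least 25% below the lower
peak), otherwise the conventional 1.5 mm/s default is returned with a
warning. The exact break-finding procedure used on real data is not
recoverable from the measurement description alone, so the fixed
default is always available and is what `extract_profile()` uses unless
told otherwise.

### The boldness index

Boldness is the sum of two within-group z-scores (group = sex ×
strain, sample SD with the n−1 denominator, conventional for small
behavioral groups): z(percent explored) + z(bottom distance) — the two
NTT measures that best separate bold from shy fish. Whether the two
z-scores should be summed or averaged is underdetermined; the sum is
used because the mean differs only by a factor of 2, which no
correlation or rank-based analysis downstream can see.

## The statistical battery

Every test is normality-gated with Shapiro–Wilk at α = 0.05, matching
standard practice for this assay family:

* **Correlations** (`correlation_auto`): Pearson's r when both
  variables pass the gate, Spearman's ρ otherwise (tie-corrected
  approximation when ties are present). The spearman branch is
  invariant under strictly increasing transforms.
* **Repeatability** (`icc_oneway`): one-way random-effects,
  single-measure ICC over two sessions, with a percentile CI from
  resampling subjects with replacement (default 1000 resamples). The
  one-way single-measure form is the simplest estimator consistent
  with "ICC of two unlabeled sessions"; users comparing against
  mixed-model repeatability should expect small differences in
  unbalanced settings. Degenerate between-subject variance can push
  the estimate below zero; it is reported as computed and flagged, not
  truncated.
* **Factorial comparisons** (`perm_anova_2x2`): fixed-effects 2×2
  ANOVA with interaction. Type II sums of squares are used so that
  main effects are adjusted for each other under unbalance (identical
  to Type I when balanced — a property the tests assert). The null
  distribution permutes the raw response wholesale, which is exact
  under the global null actually being tested and verifiable by
  enumeration on tiny inputs; residual-permutation schemes were
  considered and rejected as harder to validate. P-values carry
  add-one smoothing, `p = (1 + #{F* ≥ F}) / (1 + n_perm)`, so they are
  never zero. η² = SS~term~/SS~total~ comes from the observed
  decomposition.
* **Two-group tests** (`two_group_test`): Welch's t or Mann–Whitney U
  (unpaired), paired t or Wilcoxon signed-rank (paired; the
  differences are what gets gated). The signed-rank test is the only
  coherent nonparametric choice for paired data. Exact small-sample p
  below 26 per group without ties; tie- and continuity-corrected
  normal approximation otherwise. Cohen's d uses the classical
  pooled-SD denominator (a Welch-averaged variant is available via
  `d_method = "welch"`), attached to unpaired comparisons.
* **Effect-size bands** (`classify_effect`): small 0.01 < η² < 0.06 /
  0.2 < d < 0.5; medium 0.06 ≤ η² < 0.14 / 0.5 ≤ d < 0.8; large η² ≥
  0.14 / d ≥ 0.8; below-small is "negligible". Boundary values follow
  these inequalities exactly.
* **Multiplicity**: the correlation screen reports raw p-values, the
  convention for this assay's per-cell screens; `add_bh_column()`
  appends a Benjamini–Hochberg column for readers who want one.

## The cohort simulator

The simulator is first-class, tested code: it defines the study
conditions under which the pipeline's guarantees are checked.

**Latent structure.** Each fish carries a (metabolic, boldness) trait
pair drawn bivariate standard normal at correlation `rho_true` — the
planted POLS association — plus a log-normal mass per sex (default
medians 0.9 g female / 0.6 g male, sdlog 0.2: positive, realistically
skewed, females heavier).

**Respirometry.** True consumption is
`rmr_per_gram · mass^0.8 · exp(0.25 · metabolic_trait)`, times a
fasting multiplier (default 0.8) for unfed fish. The allometric
exponent 0.8 is intermediate metabolic scaling — larger fish consume
more O~2~ without asserting isometry — and fully configurable. Both
chambers start near air saturation (7.9 mg/l at ~27.5°C facility
water) and share the blank drift (default 0.1 mg/l/trial); each of the
four meter readings gets independent Gaussian error (default SD 0.12
mg/l). These defaults were calibrated analytically, before any test
was run, to place day-to-day repeatability of consumption near ICC ≈
0.8: with `rmr_per_gram = 1.75` a 0.8 g fish consumes ≈ 1.4 mg/l per
trial; mass and trait dispersion give a between-fish SD ≈ 0.33 of the
mean (≈ 0.50 mg/l) while four-reading noise gives a within-fish SD of
2 × 0.12 = 0.24 mg/l, hence ICC ≈ 0.25/(0.25 + 0.058) ≈ 0.81. Sessions
whose configured drop would exceed the available oxygen are flagged
invalid (anoxia) rather than silently clipped.

**Movement model.** Behavior is generated by the simplest process that
expresses all six measured behaviors: a persistent random walk
(AR(1) velocity, persistence 0.9 at 30 frames/s, stationary per-axis
speed SD = `speed_scale`, default 25 mm/s) whose vertical coordinate
mean-reverts toward a preferred height z\* (rate 1 /s), gated by a
two-state moving/frozen Markov chain (onset 0.05 /s, offset 0.5 /s,
≈ 9% time frozen), with reflecting walls so containment is
unconditional. Boldness enters through exactly two channels — the
preferred height fraction (logit shift, 0.8 per trait SD around a
baseline of 0.35 of tank height) and the speed scale (log-linear,
0.25 per trait SD) — so that the two ingredients of the boldness index
are its direct readouts, monotonically. A zero `speed_scale` disables
all displacement, including the vertical drift: propulsion scales
every movement channel, giving a clean degenerate case. The frame rate
default of 1/30 s is a plain assumption (typical depth-camera rate),
stated as such in the parameter documentation; no distributional claim
about real trajectories depends on it.

The movement loop is implemented in C++ (via Rcpp) using R's RNG, so
simulation is fast and bit-reproducible under `set.seed()`; a
full-length 6-min trajectory (10,800 frames) simulates in ~4 ms.

**What the simulator does not emulate.** Real tracked trajectories
carry pose-estimation jitter, occasional identity or depth errors, wall
occlusions, and non-stationary habituation dynamics within the trial;
frozen fish here are exactly stationary rather than jittering around a
point. Passing recovery tests on simulated cohorts therefore
demonstrates that the pipeline is correct and calibrated *under the
stated generative model*, not that any particular biological effect
exists in real fish — the analysis of real data inherits only the
arithmetic guarantees, not the effect sizes.

**Designs.** `generate_cohort()` mirrors the factorial default (TU/WIK
× female/male, ~30 per cell, two consecutive respirometry days).
Fasting can be planted as a *crossover* (each fish one fed and one
unfed respirometry session, alternating order across fish) or
*between-groups* (balanced fed/unfed split, the behavioral design);
fasting scales metabolism only, because that is the planted truth the
analysis should and should not find in behavior.

## Numerical and design choices

* Determinism: every stochastic operation takes a seed; cohort
  generation derives independent per-fish child seeds from the master
  seed, so single fish are reproducible in isolation. Bootstrap and
  permutation draws restore the caller's RNG state.
* Voxel binning uses `floor(coordinate / cell width)` with the top
  boundary clamped into the last cell; tests pin boundary behavior.
* The Type II SS machinery precomputes thin-QR factors of the four
  nested design matrices once and evaluates all permutations as one
  matrix product, which is what makes 10,000 resamples cheap.
* Ties in Spearman or rank tests fall back to documented corrected
  approximations; exact enumeration is used only where it is exact.
* Degenerate inputs (constant responses, zero-variance groups,
  all-zero paired differences, < 2 frames, < 20 speeds) are rejected
  with named errors rather than propagating NaN.

## Problem sizes used in the validation suite

The test suite validates calibration claims at sizes chosen to make
sampling bands tight while keeping the suite quick to run: 100 random
trajectories against naive-loop oracles; 200 replicate cohorts for
correlation planting; 200 replicates of n = 200 subjects (500
bootstrap resamples each) for ICC recovery and coverage; 500 null and
400 effect datasets at 1000 permutations each for ANOVA calibration
and power; and 100/20/20 full simulated cohorts (rho_true = 0 / 0.3 /
0.6) for the correlation-screen false-positive rate and recovery. The
screen-recovery oracle uses an attenuation factor λ = 0.807 (the
expected per-cell correlation is λ·rho_true, since the boldness index
and RMR are noisy readouts of their latent traits), estimated once
from a large independent simulation and frozen.

## Known limitations

* The simulator plants linear (Gaussian-copula) trait associations
  only; nonlinear or threshold POLS structures are out of scope.
* The ICC is the one-way single-measure estimator; session-fixed
  effects (systematic day-2 shifts) fold into within-subject variance
  rather than being modeled.
* The permutation ANOVA tests exchangeability of raw responses; it is
  not an exact test of one main effect in the presence of another
  large one (the classical caveat of raw-data permutation).
* No temperature/salinity correction of O~2~ solubility, no
  intermittent-flow respirometry, no social or hydrodynamic effects,
  no video or pose synthesis.
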