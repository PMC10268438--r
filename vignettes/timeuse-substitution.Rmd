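---
title: "Compositional isotemporal substitution for 24-hour movement behaviours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional isotemporal substitution for 24-hour movement behaviours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tuscoda)
```

## The scientific problem

A day always has 24 hours. Time spent asleep, sedentary (SB), in light
physical activity (LPA) and in moderate-to-vigorous physical activity
(MVPA) therefore carries only *relative* information: one behaviour can
increase only at the expense of the others. Regressing a health outcome on
one behaviour's absolute duration while "adjusting" for the others is
ill-posed — the durations are collinear by construction and live on a
simplex, not in Euclidean space.

`tuscoda` implements the standard compositional solution for longitudinal
time-use epidemiology. The 4-part day is closed to 24 h, mapped to three
pivot isometric log-ratio (ilr) coordinates, and the *change* in those
coordinates between baseline and follow-up is used to predict follow-up
levels of an outcome (here, inflammatory markers such as complement
factors C3/C4, leptin or TNF-alpha), adjusting for baseline composition
and covariates. Fitted coefficients are then translated into isotemporal
substitution estimates: the predicted change in the marker if a fixed
number of minutes per day moved from one behaviour to another, everything
else held fixed.

## From accelerometer counts to a composition

SB, LPA and MVPA come from vertical-axis accelerometer counts; sleep from
a self-reported bed/wake question (devices are removed overnight, so sleep
is never derived from wear time). The processing rules are:

* **Reintegration** (`reintegrate()`): counts are summed into the working
  epoch length, 10 s by default in cohort use.
* **Non-wear** (`detect_nonwear()`): any window of at least 60 consecutive
  minutes of zero counts, allowing at most 2 minutes with a per-minute
  total strictly below 100 counts, is non-wear; all qualifying windows are
  unioned. The rule operates on per-minute totals because it is stated in
  counts per minute. The scan is a linear-time two-pointer sweep; the test
  suite proves it equivalent to brute-force window enumeration.
* **Cut-points** (`classify_epochs()`): SB 0–99, LPA 100–1999, MVPA
  >= 2000 counts per minute, scaled proportionally to the epoch length
  (`cpm * epoch_s/60`), so at 10-s epochs the SB/LPA boundary is 100/6.
  At 60-s epochs the printed per-minute bins are reproduced exactly.
  Whether cut-points are applied at 10 s or after re-aggregation to 60 s
  is configurable; proportional scaling at the working epoch is the
  default.
* **Valid days** (`filter_valid()`): a day counts if it has >= 10 wear
  hours; a participant-wave is retained with >= 3 valid days including a
  weekend day. Averages over valid days are unweighted (no 5:2
  weekday/weekend weighting, since none is part of the protocol).
* **Closure** (`build_composition()`): self-reported sleep (hours) and the
  averaged behaviour minutes are linearly adjusted to 24 h — every part is
  multiplied by `24/total`, i.e. unaccounted time is proportionally
  redistributed over all four behaviours. Zero durations are first
  replaced by 1 minute with the positive parts shrunk multiplicatively so
  the total is preserved; log-ratios require strictly positive parts. The
  alternative of constraining waking behaviours to `24 - sleep` is noted
  but not implemented: all four parts are closed jointly.

A final partial minute at the end of a series is ignored by the non-wear
rule (which needs whole minutes) but still counts as worn time.

## Pivot ilr coordinates

For a composition \(x = (x_1,\dots,x_D)\) with a chosen part order, the
pivot ilr coordinates are

\[ z_j = \sqrt{\tfrac{D-j}{D-j+1}}\,
   \ln\frac{x_j}{\left(\prod_{k=j+1}^{D} x_k\right)^{1/(D-j)}},
   \qquad j = 1,\dots,D-1 . \]

The first coordinate carries all relative information about the first
part, which is why the descriptive paired test (`paired_pivot_ttest()`)
rotates each behaviour to the front before testing its change. The map is
an isometry between the Aitchison geometry of the simplex and Euclidean
space; the full coordinate set spans the same space under any part order,
so downstream substitution estimates are invariant to the order (tested to
1e-9 under all 24 permutations). All logarithms are natural. The default
order is (sleep, SB, LPA, MVPA).

Descriptive summaries use the compositional centre: part-wise geometric
means re-scaled to 24 h (`mean_composition()`). The confidence interval
for one part's re-scaled geometric mean (`rescaled_geomean_ci()`) is a
log-scale t interval, exponentiated and multiplied by the point
estimate's closure factor. The construction behind the published
descriptive intervals is not documented, so this choice is isolated
behind one function; Monte-Carlo calibration shows it is nominal for the
minor parts and mildly conservative for the dominant part (the closure
factor co-moves with that part's geometric mean), so coverage is always
at least the nominal level in our checks.

## The longitudinal model

For one marker, `build_design()` assembles, per participant:

* outcome: follow-up marker level;
* exposures: the three ilr *changes* (follow-up minus baseline);
* adjustment: baseline ilr coordinates, baseline marker level, sex, age,
  maternal education (5 categories, "no formal education" reference),
  zBMI and its change, pubertal stage (5 Tanner categories, stage 1
  reference), and accelerometer wear time at both waves (hours,
  uncentred — unstandardised coefficients are what the substitution
  formula consumes).

That is 22 design columns including the intercept. Analysis is
complete-case; dropped identifiers are reported. A category with no
participants contributes no indicator column (and if a reference level is
empty the first present level becomes the reference) — otherwise the
design would be rank deficient; both adjustments are messaged.

`fit_marker_model()` offers two estimators:

* **OLS** with the classical covariance \(\hat\sigma^2 (X'X)^{-1}\);
* **Huber M-estimation** (default), tuning constant 1.345 (95% Gaussian
  efficiency), solved by iteratively reweighted least squares with the
  scale re-estimated each iteration as the normalised median absolute
  residual, and the standard M-estimator sandwich covariance. Huber IRLS
  was chosen over MM-estimation because it is fully specifiable from
  first principles and its contract is directly testable; the suite
  cross-checks it against an independent M-estimation routine.

Convergence is declared when the *fitted-value* vector changes by less
than 1e-8 in relative Euclidean norm (at most 200 iterations). Fitted
values — unlike coefficients — are invariant to reparameterisations of
the ilr basis, so runs under different part orders stop at the same
iterate and the part-order invariance above holds by construction, not by
accident of a stopping rule. A zero-residual (noise-free) problem
short-circuits to the least-squares solution with a zero covariance.
Degrees of freedom are `n - p` for both methods, and the substitution
intervals use t quantiles with those degrees of freedom.

## Isotemporal substitution

Starting from a reference composition (by convention the cohort's mean
baseline composition), `reallocate()` moves `m` minutes from one
behaviour to another, leaving the other parts and the 24-h total
untouched — no re-closure is applied because the transfer preserves the
total by construction, and infeasible transfers (that would exhaust the
source behaviour) are errors, never clamps: clamping would silently
change the estimand. The predicted marker change is the linear contrast

\[ \hat\Delta = \big(z(\text{reallocated}) - z(\text{base})\big)'\,
   \hat\beta_{\Delta\text{ilr}}, \]

with a 95% t interval from the corresponding quadratic form of the
coefficient covariance; an estimate is flagged significant when the
interval excludes zero. No multiplicity adjustment is applied across the
grid or across markers, matching the interval-based decision rule.
`substitution_table()` evaluates all 12 ordered behaviour pairs at 10, 30
and 60 min/day. Because the contrast is a log-ratio, effects are *not*
proportional to the transferred minutes (the 60-min effect is not six
times the 10-min effect), and intervals widen with duration.

## The synthetic cohort generator

No individual-level cohort data are distributed, so `simulate_cohort()`
generates cohorts with known ground truth; its defaults *are* the study
conditions used in all calibration tests:

* n = 296 participants;
* baseline compositions follow a logistic-normal law: multivariate normal
  pivot-ilr coordinates, centred on the published re-scaled geometric
  means (sleep 9.13, SB 10.89, LPA 2.93, MVPA 1.05 h/day —
  `reference_timeuse_means()`); the ilr standard deviations (0.12, 0.18,
  0.30) are calibrated so the implied dispersion of part durations
  matches the published descriptive confidence intervals at n = 296;
* the ilr change is drawn with mean equal to the ilr difference of the
  published follow-up and baseline centres and standard deviations
  (0.10, 0.15, 0.25), somewhat tighter than the cross-sectional spread,
  as 3-year within-person changes are;
* covariate marginals match the published sample description (49% girls,
  age 12.8 +/- 2.4 y, the published maternal-education and
  pubertal-stage frequencies, zBMI 0.62 +/- 1.09, wear time
  14.43 +/- 1.05 h baseline and 14.32 +/- 1.22 h follow-up, baseline
  marker 89.35 +/- 27.82 on the complement-factor scale);
* the follow-up marker is the regression design times a known coefficient
  vector plus Gaussian noise (SD 20 marker units). The ilr-change
  coefficients are sized so 60-min reallocation effects are of the order
  of a few marker units — comparable to the published complement-factor
  tables — and are labelled illustrative, not empirical estimates.
  Optionally a fraction of residuals is contaminated by symmetric
  variance inflation (default multiplier 5); symmetric contamination
  isolates robustness from bias.

The logistic-normal law is the natural companion of an ilr analysis: the
implied true substitution effects are available in closed form
(`true_substitution_effect()`), which is what makes parameter-recovery
and interval-coverage experiments possible. What the generator does *not*
emulate: school-level clustering, assay-specific measurement error,
informative missingness, or real wear-time/behaviour correlation
structure. Passing calibration tests therefore demonstrates the
correctness of the estimator under its own assumptions, not robustness to
every feature of field data.

`simulate_counts()` turns a block schedule of non-wear/SB/LPA/MVPA into an
epoch count series with counts drawn strictly inside the scaled cut-point
bins, planting up to two sub-threshold "allowance" minutes inside
non-wear blocks. One identifiability constraint is worth stating: at any
epoch length a pure-SB minute necessarily totals under 100 counts, so SB
minutes bordering a non-wear block can legitimately be absorbed by the
allowance rule. `random_day_schedule()` therefore borders every non-wear
block with LPA or MVPA; this is a property of what is recoverable from
counts, not of the detector. `simulate_study_bundle()` writes a complete
on-disk study (count CSVs realising each participant's composition with
overnight device removal, a jittered sleep-report CSV, covariates and
markers) for end-to-end pipeline tests.

## Numerical choices and degenerate inputs

* Closure and zero replacement are exact in the sense that totals are
  preserved to machine precision; closure is idempotent and
  scale-invariant.
* Equal bed and wake times are rejected (0 h and 24 h sleep are
  indistinguishable); wake times at or before bedtime wrap midnight.
* A paired pivot test with constant non-zero differences (zero variance)
  is an error rather than an infinite t statistic; identical waves return
  t = 0, p = 1.
* Reallocation is computed in hours with plain IEEE arithmetic. A
  transfer and its reverse cancel to within one unit in the last place
  always, and bit-exactly unless the addition crosses a binary exponent
  boundary (e.g. adding 1 h to 1.05 h lands in [2, 4), where the spacing
  of representable numbers doubles and the last bit of the original value
  is irrecoverably rounded). No representation in hours or minutes avoids
  every such case, so exact restoration is asserted only where it is
  representable; untouched parts are always bit-identical.
* Simulation problem sizes used by the shipped checks — 500 replicates
  for interval coverage, 200 for the contamination comparison, 200 random
  series for the non-wear oracle, 100 planted schedules — were chosen to
  give Monte-Carlo error well inside the decision margins while keeping a
  full run in the order of a minute.

## Worked example

```{r example, eval = FALSE}
library(tuscoda)

# a synthetic study, written to disk like a real one
dir <- tempfile()
simulate_study_bundle(dir, n = 36, seed = 21)

res <- run_all(list(
  counts_dir = file.path(dir, "counts"),
  sleep_csv  = file.path(dir, "sleep.csv"),
  cohort_csv = file.path(dir, "cohort.csv"),
  out_dir    = file.path(dir, "out"),
  markers    = "c3"))

res$descriptive          # Table-2-style behaviour and marker summary
res$substitutions$c3     # full reallocation grid with 95% CIs
```

## Limitations

* The robust estimator and the descriptive-interval construction are
  reasonable, documented choices, not assertions about what any
  particular published analysis used.
* Only 4-part compositions are tuned, although the ilr machinery accepts
  any D >= 2.
* One-to-one reallocations are theoretical contrasts; they need not
  correspond to attainable behaviour change.
* Raw device formats (.gt3x/.agd), vector-magnitude processing and bout
  detection are out of scope; input is timestamped count CSVs.
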