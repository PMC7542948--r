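---
title: "A complexity battery for single-subject EMA time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A complexity battery for single-subject EMA time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emacomplexity)
library(dplyr)
```

## The question the battery answers

Ecological momentary assessment (EMA) collects repeated in-the-moment
self-ratings — mood, symptoms, physical sensations — several times a day from
a single person. If such a person is usefully described as a complex dynamical
system, their self-ratings should carry three statistical signatures:

1. **Memory** — ratings depend on past ratings, over short *and* long lags,
   and that dependence itself drifts over time;
2. **Regime shifts** — the distribution of ratings changes abruptly when the
   person transitions between attractor states (e.g. into a depressive
   episode), often preceded by *flickering* between the old and new regime;
3. **Sensitive dependence on initial conditions** — trajectories that start
   close together diverge, so ratings are predictable a few steps ahead but
   not far ahead.

The package implements one tested procedure per signature and an orchestrator
(`run_battery()`) that applies all of them to every item of a dataset, both
over the full measurement period and over a pre-specified baseline window,
with Bonferroni-corrected significance. Because raw clinical EMA data cannot
ship with a package, a synthetic generator (`generate_study_like_dataset()`)
produces datasets of the same shape with *known* ground truth, so every
marker can be validated against planted structure.

## Data model

An `ema_df` is a long tibble — one row per (assessment, item) cell — with a
`missing` flag and per-item native scale bounds. Two conventions matter:

* **Time is assessment rank.** Beeps are treated as equally spaced (index
  0, 1, 2, ...); every test below assumes a regular index. Clock time is not
  modelled.
* **Missing cells are excluded listwise within each univariate analysis**
  (the markers see a compacted series), with two exceptions: the ACF skips
  only the lagged products that touch a missing cell, and the simplex
  forecaster imputes missing cells itself (see below). Missingness in the
  motivating setting is sparse (~0.24% of cells), so these choices are
  essentially inconsequential there.

`rescale_items()` maps bipolar (−3..+3) and Likert (1–7) items onto a common
1–7 range before descriptives; all markers except the mean/SD are invariant
(ACF, PACF, KPSS, Bartels, forecast skill) or equivariant to that affine map.

## Marker 1: memory

**Bartels rank test** (`bartels_test()`). The rank von Neumann ratio
RVN = Σ(R~t~ − R~t+1~)² / Σ(R~t~ − R̄)² has expectation 2 under
exchangeability; positively dependent series push it below 2, alternating
series above. We use midranks for ties (7-point scales produce many), the
exact null variance 4(n−2)(5n²−2n−9)/(5n(n+1)(n−1)²), and a two-sided normal
test: non-randomness in either direction counts. Calibration on
Likert-discretized white noise is checked in the test suite (type-I error at
most 1.5× nominal despite heavy ties).

**ACF/PACF profiling** (`acf_profile()`). Sample autocorrelations with
overall-mean centering and lag-0 normalization; PACF by Durbin–Levinson. The
significance threshold is the two-tailed z bound z~1−α/2~/√n with the series
length as the number of observations *at every lag* — a deliberate
convention, not n−k. Long-range memory is summarized as the number of
significant partial autocorrelations and the largest significant lag
(`summarise_acf_profile()`); the battery scans lags up to n/3 so findings at
very high lags (lag > 200 on a 1476-point record) are visible. Note that at
α = .05 roughly 5% of scanned lags are expected to flag by chance, so these
counts describe, they do not test.

**Moving-window ACF** (`moving_window_acf()`). The ACF recomputed in
`floor((n − w)/step) + 1` windows (e.g. 985 maximally overlapping windows of
492 points in a 1476-point record), summarized per lag by median and
interquartile range; wide IQRs expose non-stationary correlation structure.
Constant windows are flagged degenerate rather than failing the run.

**Time-varying AR(1)** (`tvar_fit()`). The model
y~t~ = β₀(t) + φ₁(t)·y~t−1~ + ε~t~ with both curves expanded in cubic
penalized B-splines (basis dimension 10 per curve, second-difference
penalty), fitted with `mgcv::gam()` and GCV-selected smoothing. Lag 1 is
used because it is the dominant and most-studied lag in EMA data. The
penalty's null space holds constant and linear coefficient paths, so the
effective degrees of freedom (EDF) of the varying-coefficient term is about
2 when φ₁ is constant or drifts linearly and exceeds 2 when the
autocorrelation is definitely time-varying. `smooth_p` is mgcv's approximate
significance test of the smooth term (whether the time-varying coefficient
function differs from zero) — the standard test reported with this model;
EDF-based classification (>2 vs ≤2) is the primary non-stationarity
criterion, and EDF values should be compared qualitatively, as they depend
mildly on basis and penalty choices.

## Marker 2: regime shifts

**KPSS level-stationarity test** (`kpss_level_test()`). Cumulative sums of
demeaned ratings, normalized by a Bartlett-kernel long-run variance with the
short truncation lag floor(3√n/13). The p-value is interpolated in the
standard critical-value table and therefore lives in [.010, .100]; .010 is
the significance bound (the battery flags KPSS at that bound, not at the
Bonferroni level, since the clamped p cannot reach it).

**Energy-statistic divisive change points** (`e_divisive()`). Hierarchical
divisive search maximizing the scaled energy divergence between candidate
segments (moment index α = 1), with significance per split from a
permutation test within the current segment structure (199 permutations,
add-one p estimator so p is never exactly 0, stop at p > .05, minimum
segment 30). The split-scan kernel is compiled (Rcpp) because the
permutation test repeats the O(n²) scan hundreds of times per split. The
statistic is sensitive to changes in mean, variance, or any distributional
feature. Defaults follow the algorithm's common usage; change-point *counts*
on noisy data are inherently stochastic and should be read as such.
Missing values are dropped with positions closed up; change indices are
reported in both coordinates.

## Marker 3: sensitive dependence on initial conditions

**Delay embedding + simplex projection** (`delay_embed()`,
`simplex_forecast()`). The series is embedded with time-lagged copies as
surrogate state-space dimensions (study configuration: E = 13 dimensions,
delay τ = 4). Vectors from the first 700 observations form the library; each
later vector is forecast tp steps ahead by the weighted mean of the futures
of its E + 1 nearest library neighbours, with weights exp(−d/d~min~).
Forecast skill at horizon tp is the Pearson correlation between forecasts
and observations; `decay_slope()` fits an OLS line to skill over horizons
1–5. Deterministic periodic signals hold skill ≈ 1 at all horizons, white
noise has skill ≈ 0 everywhere (so a flat, near-zero decay slope), and
chaotic dynamics show high short-term skill that decays — the three-way
contrast that diagnoses sensitive dependence.

Numerical conventions: prediction vectors never enter the library (the hard
700-point split already prevents leakage, so no Theiler window is applied
inside the library); neighbour futures must themselves lie inside the
library; distance ties break toward the earlier library index; when the
nearest distance is exactly 0 all E + 1 weights are set to 1. Missing
observations are imputed *within this analysis only* by the forecaster's own
neighbour-weighted one-step estimates (initialized by linear interpolation),
mirroring how this algorithm is normally run; the rest of the battery never
sees imputed values.

A caution from our own validation: how fast a chaotic signal loses skill
depends on how densely the library samples the attractor. The logistic map
at full chaos (r = 4) loses over half its skill by horizon 8 under the study
configuration, but at r = 3.9 a 700-point library tracks it almost perfectly
through horizon 8 — weakly chaotic systems need longer horizons or sparser
libraries before decay is visible.

## The synthetic generator

`generate_series()` provides the ground-truth processes the battery must
discriminate: IID noise (Gaussian/uniform), AR(1) (short memory), exact
fractional Gaussian noise via circulant embedding (long memory with a
closed-form autocovariance, which the test suite checks by Monte Carlo),
piecewise regimes with planted change points and a pre-shift flicker window
(alternating regime draws with geometric dwell times, mean 5 assessments —
flickering is only ever described qualitatively, so this is our concrete
model of it), sine waves, and the logistic map. Likert discretization maps
affinely to 1..L and rounds half-up, preserving the latent ordering.

`generate_study_like_dataset()` fixes the study-shaped conditions: 29 items ×
1476 assessments, baseline window of 292; 9 AR(1) items (φ ~ U(0.35, 0.7))
and 9 fGn items (H ~ U(0.65, 0.85)) standing in for psychological states,
3 regime items with flicker (shifts placed after the baseline window,
since regime shifts during a stable baseline should be rare), 8 white-noise
items standing in for physical sensations; item means U(1.5, 4.5) and SDs
U(0.5, 1.1) on the 1–7 scale (the range observed in real EMA items, floored
at 0.5 so rounding cannot create zero-variance items); missingness
103/(29×1476) ≈ 0.24%. Everything is reproducible from one seed, down to the
CSV bytes.

What the generator does *not* emulate: cross-item coupling (items are
generated independently), diurnal cycles and unequal beep spacing,
informative missingness, and multiplicative cascade dynamics (no accepted
generative model exists for the "interactions across time scales" reading of
time-varying autocorrelation, so no such kind is shipped). Passing the
battery on synthetic data therefore validates the *statistics*, not any
claim about real patients.

## Battery conventions

* Bonferroni threshold: `alpha / n_items`, rounded **half-up to 3 decimals**
  (.05/29 → .002) — an idiosyncratic but faithful convention; the raw ratio
  is kept as an attribute.
* The battery runs twice — full period and baseline subset — and interleaves
  both in one report row per item. Items with zero baseline variance are
  dropped from the subset analyses only (their subset cells are `NA`).
* Decay slopes are computed on the full period only: a 292-point baseline
  cannot host a 700-point library.
* Per-item failures (constant series, too-short windows) are recorded in the
  row's `notes` and never abort the batch.
* Reports: TSV with separate asterisk columns for significance (never glyphs
  inside numbers) plus a full-precision JSON companion echoing the
  configuration. Reruns with the same config seed are byte-identical.

## Worked example

```{r example, eval = FALSE}
d <- generate_study_like_dataset(n_items = 29, n_timepoints = 1476, seed = 7)
report <- run_battery(d, battery_config(seed = 8))
report |>
  dplyr::left_join(ground_truth(d)[, c("item", "kind")], by = "item") |>
  dplyr::group_by(kind) |>
  dplyr::summarise(pct_nonrandom = 100 * mean(bartels_sig_full),
                   mean_decay = mean(decay_slope))
```

Memory-bearing items (AR(1), fGn) come out non-random with negative decay
slopes; white items are rarely flagged and have near-zero slopes; regime
items carry the change points — the synthetic analog of the
psychological-versus-physical contrast the battery is designed to expose.

## Problem sizes used in validation

The shipped tests validate: Bartels calibration on 2,000 replicates at each
study length (292 and 1476); e-divisive false positives on 200 IID series of
600 points and localization on 40 planted 2-SD shifts; KPSS retention on 200
IID series of 1,000 points; TV-AR EDF behaviour over 50 seeds at n = 1476
(medians reported, since GCV occasionally undersmooths a single replicate);
simplex forecasts against a brute-force oracle (agreement to 1e−10) and the
deterministic/chaotic/random three-way contrast over 10 seeds; fGn
autocovariance over 50 replicates at n = 10,000 using the uncentered
estimator (the demeaned sample ACF is biased downward under long memory).
These sizes make every check reproducible on a laptop in a few minutes.

## Known limitations

* The TV-AR EDF is compared qualitatively across software: different bases,
  penalties or smoothing selectors shift EDF values, though rarely across
  the EDF = 2 boundary.
* PACF significance counting at α = .05 over hundreds of lags is descriptive;
  about one lag in twenty flags by chance.
* Change-point counts depend on `min_segment`, the permutation count and the
  stopping rule; only the planted-shift localization is a sharp quantity.
* The simplex forecaster assumes a stationary attractor within the library;
  a regime shift *inside* the library degrades forecasts in ways the decay
  slope does not distinguish from chaos.
* Single-subject design: nothing here generalizes across people; the battery
  characterizes one record at a time.
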