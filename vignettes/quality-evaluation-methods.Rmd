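---
title: "Quality-centric evaluation of chromatographic data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-centric evaluation of chromatographic data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaqc)
```

## Overview

`chromaqc` turns raw chromatographic traces into a per-compound quality
table, groups the compounds into quality-sensitive clusters without labels,
and validates the grouping by the per-cluster performance of a supervised
retention-time model. This vignette documents the models, the tunable
parameters, the numerical choices, and the limits of what the bundled
simulator can show.

## Signal model and peak measurements

A trace is modelled as `Y(t) = B(t) + P(t) + N(t)`:

* `B(t)` — linear baseline (intercept + slope), fitted by least squares to
  the idle regions (everything outside the user-supplied peak windows).
  A linear form is the simplest model that detrends the common slow drift;
  the fit requires at least 10% of the grid to be idle.
* `P(t)` — a sum of exponentially modified Gaussian (EMG) peaks, the
  standard model for tailing chromatographic peaks. Each peak has a
  Gaussian centre `apex_time`, width `sigma` (minutes), apex `height`
  (of the symmetric limit) and a tailing constant `tau >= 0`; `tau = 0`
  is exactly Gaussian and the convolution preserves area
  (`height * sigma * sqrt(2*pi)`) for every `tau`.
* `N(t)` — i.i.d. Gaussian noise with standard deviation `noise_sd`,
  drawn from the run's seed.

The EMG is evaluated through the scaled complementary error function
(`erfcx`) in a two-branch form whose exponents are assembled before
exponentiation, so it is overflow-free for every `tau/sigma` ratio —
including the near-Gaussian limit, where naive `exp * erfc`
implementations fail. Beyond `erfcx` arguments of 25 a three-term
asymptotic continuation is used.

From a measured trace the package derives, per peak window:

* **apex** — grid maximum of the baseline-subtracted signal, refined by a
  three-point parabolic interpolation. The refinement matters: replicate
  retention-time jitter of 0.005 min must be measurable on a 0.005 min
  grid. For strongly tailed peaks the apex plateau is flat and baseline
  noise moves the located apex by more than one grid step; this is a
  property of the signal, not the estimator.
* **half-height widths** — first crossings of `x * apex_height`
  (default `x = 0.5`) moving outward from the apex, located by linear
  interpolation between bracketing grid points. Taking the *first*
  crossing makes the measurement robust to distant secondary peaks. At an
  exact grid-value tie the inner point is used.
* **skewness** — `Qs,0 = WR / WL`. Exactly 1 for a symmetric peak;
  fronting < 1 < tailing. The height fraction `x` is exposed because the
  statistic is defined for any `x` in (0, 1).
* **area** — trapezoidal integral of the baseline-subtracted signal
  (clipped at zero) between the points where it first falls below
  `max(0.5 * noise_sd, 1e-12 * height)` on each side, capped at the
  window. With noiseless input the bound reduces to the numerical floor.
* **SNR** — apex height over idle-noise standard deviation. Among common
  conventions (peak-to-peak noise, doubled height) this one is the most
  stable on short idle regions; a noiseless trace reports `Inf` and the
  row is flagged rather than dropped silently.
* **ΔtR** — `tR,1 − tR,2` across the replicate pair, signed; a negative
  value means the compound eluted later in the second run.

Metrics are taken from run 1 (run 2 contributes only `tR,2`); which run
supplies the metrics is configurable since either convention is
defensible. Failed measurements produce flagged rows with missing values;
`drop_incomplete()` removes them and reports what was dropped, mirroring
the practice of analysing only complete records.

## Preprocessing, PCA, clustering

The clustering features are `delta_tr`, `snr`, `skewness`, `peak_area`,
`length`, `sulfur_count`; the prediction target `tr` is never a clustering
feature. Each feature is z-scored and then min-max scaled to [0, 1],
fitted on all rows — the unsupervised setting has no held-out data to
leak into. (For the supervised per-cluster models, feature scaling for
the kernel method is refitted on the training split only.) "Normalize"
is interpreted per feature; a row-wise norm would entangle unrelated
measurements. A zero-variance feature raises a named error instead of
propagating NaNs.

PCA is applied to the centred feature matrix; the variance ratio of a
component is its eigenvalue over the eigenvalue sum. The default keeps 2
components (on the bundled simulator they explain ≈ 94% of the variance,
comfortably above the 80% rule of thumb, and make the clusters directly
plottable); a cumulative-variance threshold mode is available.

k-means uses k-means++ seeding, Lloyd iterations to a fixed point
(`tol = 1e-4` relative WCSS change, `max_iter = 300`), the best of
`n_init = 10` restarts, and repairs an empty cluster by reassigning the
point farthest from its centre. Restarts make the returned WCSS curve
non-increasing in k in practice; on small instances the solution matches
the exhaustive-partition optimum. k is chosen where the WCSS curve has
maximal discrete curvature (largest second forward difference, ties to
the smaller k); a monotone-linear curve has no elbow and says so rather
than guessing. The choice is validated by the mean silhouette
`(b − a) / max(a, b)` computed in the same PCA space with Euclidean
distances; singleton clusters score 0. Cluster labels are 1-based and
re-indexed by descending cluster-mean SNR so that "cluster 1" is always
the strongest-signal group across seeds.

## Per-cluster validation

Each cluster of at least 10 rows is split 80/20 (seeded, within-cluster —
a global split could leave a small cluster with an empty test set), and an
exhaustive grid search with cross-validated RMSE (default 5 folds, floored
at 2 with a warning) selects the regressor configuration, which is refit
on the full training split. Two families are shipped with their full
search grids: gradient-boosted trees (`max_depth` 5–50, `learning_rate`
0.001–0.2, `n_estimators` 100–1000, `max_leaf_nodes` 2–10) and RBF
support-vector regression (`C` on a logarithmic ladder 1–1000, `gamma`
0.1/0.01/0.001, `epsilon` 1e-4–2e-4). Trees are scale-equivariant and
take raw features; the kernel method gets train-fitted z-scoring. Test
RMSE and R² (about the test-set mean; undefined for a constant test
target and then reported missing) are recorded per cluster, clusters are
ranked by ascending test RMSE (ties: descending R², then index), and the
best/worst ranked clusters receive `high`/`low` verdicts. The report's
feedback section names the quality measurements with the largest
standardized mean difference (mean gap over pooled within-cluster spread)
between the best and worst cluster — effect sizes, because raw mean
ratios over-weight near-zero features such as ΔtR.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates per-compound replicate pairs from latent
quality tiers with known ground truth. Tier profiles control baseline
noise (high 0.5–1, medium 2–5, low 8–15 intensity units), tailing
(`tau` 0–0.02, 0.05–0.15, 0.2–0.5 min), replicate retention jitter
(sd 0.005, 0.02, 0.1 min) and peak height (950–1050, 570–630, 330–370).
The jitter applies to *every* injection — run 1 elutes at the nominal
retention time plus one draw, run 2 at run 1 plus another — so
irreproducible tiers have genuinely irreproducible retention times, which
is what degrades their supervised models downstream.

Chemistry is tier-linked: high-quality compounds are long (16–20 nt) and
lightly phosphorothioated (0–15% of linkages), medium ones short (5–9 nt)
and partially modified (40–60%), low ones long and fully modified
(85–100%). This mirrors the cluster chemistry observed in real IPLC
datasets of antisense oligonucleotides, where the well-behaved cluster is
long and unmodified, a short partially-modified cluster sits in between,
and heavily sulfur-modified sequences form the poorest group. It is a
deliberate design decision with a consequence worth stating plainly: in
this simulator, chemistry is informative about quality. If length and
sulfur were drawn independently of tier, min-max scaled length would be a
full-range noise dimension and k-means would partition by length rather
than quality — a configuration under which no method could recover the
tiers from these six features.

The nominal retention time follows
`tr = 1.5 + 0.35 * length + 0.10 * sulfur_count + N(0, 0.01)` minutes —
a smooth, learnable trend with a small compound-specific deviation.
Rendering uses a 0–25 min window at 0.005 min sampling (5001 points),
which resolves half-height crossings to well under 1% for
`sigma >= 0.05`; the default peak width is `sigma = 0.06` min. One master
seed drives everything through deterministic sub-stream seeds
(a fixed multiplicative counter scheme), so cohorts are reproducible
element-wise and a rerun writes byte-identical artifacts.

What the simulator does **not** emulate: co-eluting/overlapping peaks,
mass-spectral dimensions, gradient-program effects, non-Gaussian or
correlated detector noise, nonlinear baselines, and outlier injections.
Passing tests on synthetic cohorts therefore demonstrate that the
measurement and clustering machinery is correct and that the pipeline
recovers planted structure; they do not certify performance on real
instrument data, where quality tiers are not discrete and chemistry is
only partially informative. Real tables (in the documented CSV dialect)
can be fed directly to the same pipeline via the `quality_table` input
mode.

## Numerical choices and degenerate inputs

* Chromatograms must be finite, strictly increasing, uniformly sampled,
  with ≥ 16 points; violations raise classed errors (`chromaqc_*_error`)
  naming the offending stage.
* The instrument sampling rate and the noise distribution are declared
  defaults, not inferred from any source: 0.005 min sampling, Gaussian
  noise. Both are configurable.
* Apex detection requires the apex to exceed `snr_floor * noise_sd`
  (default floor 3); an all-zero window is a no-peak error.
* Quantiles in cluster summaries use linear interpolation (type 7);
  standard deviations are sample (n−1) and reported missing for
  single-row clusters.
* Quality tables round-trip through CSV at 12 significant digits.
* Problem sizes in the test suite (cohorts of 300 compounds, 20 seeds,
  boosting grids reduced to `n_estimators = 100` with 3 folds) were
  chosen to exercise the full pipeline at a scale where the planted
  effects are comfortably detectable; the full grids are available for
  larger studies.

## Known limitations

* Single-peak windows only: overlapping peaks are not deconvolved, and a
  window containing two peaks will measure their envelope.
* The linear baseline under-fits strongly curved gradients; the
  measurement interface accepts any per-point baseline vector if a
  different estimator is fitted externally.
* The elbow criterion needs at least 4 WCSS points and a genuine
  curvature maximum; flat geometries are reported as errors, not guessed.
* Silhouette computation is O(n²) in memory and time; at the intended
  scale (hundreds to a few thousand compounds) this is negligible.
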