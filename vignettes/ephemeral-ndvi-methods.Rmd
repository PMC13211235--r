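---
title: "Methods: extracting and analyzing the ephemeral-plant NDVI signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extracting and analyzing the ephemeral-plant NDVI signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephemNDVI)
```

## The signal and its model

Early-spring ephemeral plants in cold arid deserts germinate on snowmelt,
grow explosively, and senesce before summer. On an 8-day NDVI composite
grid spanning day-of-year (DOY) 65–225, a pixel dominated by ephemerals
shows a flat late-winter background, a steep rise to a spring peak, a steep
fall to a post-peak minimum, and then a mild secondary rise as xerophytic
shrubs green up. Three key points anchor the analysis per pixel-year:

* `DOYa` — the peak: global maximum of the seasonal series (earliest
  composite on ties);
* `DOYb` — the post-peak minimum: minimum over composites strictly after
  the peak (earliest on ties);
* `DOYc` — the regreening onset: minimum over composites strictly before
  the peak, taking the **latest** composite on ties.

The onset rule deserves a comment, because "regreening onset" admits
several operationalizations and the key-point framework itself fixes none.
We define it as the pre-peak minimum; since the background before onset is
flat, ties are frequent there, and taking the latest tied composite selects
the last background value before the rise — the natural anchor for the rise
increment. The rule is a documented argument of the detector, not a
hard-wired constant.

The ephemeral contribution of a pixel-year is the life-cycle increment

$$\mathrm{NDVI}_{eph} = (\mathrm{NDVI}_a - \mathrm{NDVI}_c) +
                        (\mathrm{NDVI}_a - \mathrm{NDVI}_b),$$

the regreening rise plus the senescence decline. It is nonnegative whenever
the key-point ordering holds, zero exactly for a curve flat over
`[DOYc, DOYb]`, and robust to the late-summer xerophyte signal, which
contributes to neither term. Degenerate series (constant, monotone, or with
the maximum at the window edge) are flagged rather than forced into the
formula; flagged pixel-years propagate as missing values.

## Masking, classification, validation

The distribution mask uses the senescence decline `NDVIa − NDVIb`: each
pixel's multi-year mean decline is compared against the spatial mean of
those means, and pixels **strictly** above it form the distribution area.
"Mean value as threshold" is genuinely ambiguous between this global
reading and a per-pixel self-threshold; we default to the global mean
(`mode = "global_mean"`) and keep a `per_pixel` mode (a pixel is in-mask
when its annual decline beats its own mean in at least half the years) for
sensitivity checks. Strict inequality is used at the threshold and at every
class cutpoint, matching the published class definitions (Medium is
NDVI *strictly* above the upper cut).

Classification into Sparse / Less / Medium uses two ordered cutpoints,
either fixed (the reference values 0.1564 and 0.1878) or recomputed by
Jenks natural breaks. The Jenks solver is the exact Fisher
dynamic-programming optimum of the within-class sum of squared deviations,
not a heuristic — on scene-sized inputs (a few thousand values) the
O(kn²) recursion is instantaneous, and tests verify it against exhaustive
partition enumeration for n ≤ 12. Values exactly at a cutpoint fall to the
lower class, so "strictly above the upper cut" is Medium, as printed.

Validation projects occurrence points onto the grid with half-open cell
bounds `[x, x + cell)` and reports, per family and overall, the share of
points inside the mask, rounded to two decimals. Off-grid points count as
outside and are tallied in a warning attribute rather than dropped
silently.

## Temporal dynamics

The annual regional mean of `NDVIeph` is segmented by piecewise linear
regression: an exhaustive search over all admissible placements of up to
four breakpoints (minimum segment length 3 years, earliest placement on
ties) minimizing the summed residual sum of squares of per-segment
least-squares lines. With ~22 annual values and three breakpoints the
search space is only C(21,3) placements, so exhaustive enumeration is both
exact and cheap; the default of three breakpoints reproduces a four-phase
segmentation. Per-segment slope p-values come from the usual t test and are
`NA` for two-point segments.

Interannual structure is decomposed by empirical mode decomposition:
sifting with cubic-spline envelopes through the local extrema
(mirror-extension of the two end extrema at each boundary), a Cauchy
stopping criterion of 0.2 with at most 100 sifting iterations per mode, and
extraction until the residual is monotone or has fewer than three extrema.
These internals follow common EMD practice; the decomposition literature
fixes none of them uniquely, so each is an argument with the stated
default. The residual is defined by subtraction, which makes the
reconstruction identity exact to floating-point. The ensemble version
(EEMD) averages the decomposition over white-noise-perturbed copies
(defaults: ensemble of 100, noise at 0.2 of the signal sd), aligning mode
counts by zero-padding; its reconstruction error shrinks like
`noise_sd / sqrt(ensemble size)`, which the tests assert at three ensemble
sizes. Per-mode variance contributions normalize component variances
(modes + residual) to 100%, and the mean period of a mode is the series
length divided by its count of local maxima.

## Spatial dynamics

Transition matrices count pixels by (class at t1, class at t2) and scale by
cell area. Pixels unclassified in either period are excluded from the
matrix and reported separately — published transfer tables whose totals
differ between period pairs imply exactly this restriction to jointly
classified pixels. Row and column sums therefore reproduce the class areas
of each period restricted to the joint support, an identity the tests
check.

Centroids are weight-weighted means of cell-center coordinates in the
projected km plane; displacement is planar Euclidean distance and bearing
is degrees clockwise from north. Planar geometry is appropriate because a
scene spans well under 300 km, where great-circle corrections are
negligible. Class centroids default to indicator (area) weights with an
NDVI-weighted option, since a published figure rarely states which
weighting it used. Stability is the per-pixel coefficient of variation of
annual `NDVIeph` with the sample (n−1) standard deviation; pixels with zero
temporal mean are flagged undefined.

## Drivers

The driver table pairs each masked pixel's period-mean `NDVIeph` with 15
environmental variables in four factor categories (temperature,
precipitation, snow, topography). Aspect is circular, so it is encoded as
northness (`cos` of the angle) by default; the encoding is switchable
because some workflows treat aspect as a plain covariate.

Relative importance uses a regression random forest (500 trees, candidate
set of ⌈p/3⌉ variables per split) and Gini (node-impurity) importance,
normalized so all variables sum to 100%; category contributions are sums
over member variables. One property of feature subsampling is worth
stating: because two thirds of the splits cannot see any given variable,
impurity credit is deliberately spread across competitors, so even a
noise-free response generated by a single variable concentrates only ~80%
of the credit under the default `mtry`. When the goal is identification
rather than ensemble averaging, pass `mtry = p` (the full candidate set),
under which the generating category takes >99%; the tests use that setting
for the identification checks and the default elsewhere.

Path analysis is a from-scratch partial least squares path model (PLS-SEM):
reflective (Mode A) outer estimation alternating with path-weighting-scheme
inner estimation until the outer weights change by less than 1e−6, path
coefficients by least squares of each endogenous latent on its
predecessors, effects decomposed into direct / indirect / total via
`solve(I − B) − I` (equivalent to enumerating all directed paths, which the
tests do independently), and `GoF = sqrt(mean communality × mean R²)`.
Coefficient p-values come from a seeded nonparametric bootstrap (200
resamples by default) with normal-approximation two-sided p-values, a
pragmatic default given that significance stars in the SEM literature
rarely state the exact procedure. Latent signs are fixed so that each
block's loadings sum positive. In the single-indicator limit every latent
equals its standardized indicator and the model collapses to classical path
analysis — the tests verify coefficient-level equality with closed-form
regression there. The pipeline's default inner structure treats topography
as exogenous, temperature as a mediator, and snow and precipitation as the
proximate moisture supplies, with all four pointing at NDVI; any acyclic
single-sink adjacency can be supplied instead.

## Projection

The projection model is a small convolutional regressor over
`patch × patch × 12` windows of the predictor stack (the 12-variable roster:
four precipitation, four snow, two temperature, elevation, aspect). The
published description of such architectures is typically schematic, so the
concrete default is documented in `cnn_config()`: two 3×3 convolution
stages with 16 and 32 filters and ReLU activations, global max pooling over
the remaining spatial positions, a dense layer of 64 units, and a scalar
linear output; mean-squared-error objective, Adam (learning rate 6e−3,
minibatch 32, up to 250 epochs), early stopping with patience 25 on a 10%
validation split. The network is implemented directly on BLAS matrix
products via im2col indexing, with gradients verified against numerical
differentiation. Two numerical choices matter in practice and are fixed:
per-channel z-score normalization computed from training-fold statistics
only (no leakage into held-out folds), and internal standardization of the
target during optimization (predictions are returned on the physical NDVI
scale) so that convergence does not depend on the numeric magnitude of
NDVI. Patches at scene edges use mirror padding.

Five-fold cross-validation reports per-fold and mean ± sd R² and RMSE; the
final model is refit on all samples. One model is trained on pooled
pixel-level targets (the multi-year mean `NDVIeph`), which keeps the
training-set definition explicit where a per-period alternative would also
be defensible. Scenario projection substitutes altered rasters for exactly
the four future-climate variables (`Pre_AU`, `Pre_SP`, `Pre_year`,
`Temp_AU`), holds the snow and topography variables at their historical
values, predicts the NDVI raster on the same grid, classifies it with the
vigor cutpoints, and tabulates class areas, shares, and the scene mean.

## The synthetic scene: what it emulates, and what it does not

The generator produces, under one master seed with fixed per-component
substreams (cube: seed+11; env raster *i*: seed+23+i; occurrences:
seed+41):

* piecewise-linear seasonal curves through (onset, peak, trough, end) —
  defaults DOY 89 / 137 / 161 on the 8-day grid. The peak and trough dates
  are the calibrated life-cycle dates of the system being emulated; the
  onset date is not reported anywhere, so it is chosen on-grid and well
  before the peak. A piecewise-linear family (rather than, say, double
  logistic) is sufficient because every downstream statistic depends only
  on the key-point values, not on curvature between them;
* a south-high/north-low amplitude gradient plus linear modulation by the
  environmental rasters, with positive snow and precipitation coefficients
  and negative temperature and topography coefficients — the qualitative
  driver structure of the system. Default NDVI levels (background 0.05,
  peak 0.18, late-summer xerophyte level 0.08) put the multi-year mean
  increment in the realistic 0.1–0.3 range; the amplitude floor keeps the
  spring peak above both background and xerophyte levels so noise-free
  extremes stay on the preset dates;
* environmental rasters as gradient or smoothed patchy Gaussian fields with
  stated means and sds in physical units, and "future" variants that add
  deltas to exactly the four substitutable climate variables;
* occurrence points concentrated in masked cells with probability
  `inside_prob`, carrying family labels from an 11-family roster with
  reference counts, deduplicated within cell and family.
* observation noise: per-composite Gaussian noise plus an interannual
  amplitude wobble, both governed by the single `noise_sd` knob (default
  0.02 NDVI units — no per-pixel noise level is published for such scenes,
  so this is a free parameter chosen at the scale of compositing residuals);
  a small deterministic trend-plus-3-year-cycle gives the annual series
  temporal structure even at zero noise.

The scene is a statistical stand-in, not a physical simulation: no dune
geomorphology, no snow physics, no spatial autocorrelation in the noise, no
mixed pixels, no cloud gaps. Consequently, passing tests demonstrate that
the algorithms implement their definitions correctly and recover planted
structure — they do not certify accuracy on real imagery, where mixed
pixels and sensor artifacts dominate the error budget. Quantities that in
the original study depend on real rasters (specific variance contributions,
importance percentages, path coefficients, centroid kilometers) are
asserted here only at the level of structure, sign, and recovery tolerance.

## Problem sizes and numerical choices

Default scenes are 32×32–64×64 cells at 1 km over 22 years — large enough
that every code path (vectorized key-point scans, patch extraction, CV
folds) is exercised with comfortable statistical power, small enough that
the full test suite runs in minutes on one core. The test suite pins: exact
reproduction of reference validation and transfer-table arithmetic;
key-point recovery on every pixel of a noise-free 64×64 scene; oracle
equality for the Jenks, segmentation, key-point, IDW, resampling, centroid
and effect-decomposition solvers; EMD reconstruction below 1e−9; chain-path
recovery within ±0.05 at n = 2000; and cross-validated R² above 0.8 for a
known smooth predictor-to-NDVI mapping.

Raster IO uses plain-text formats: ESRI ASCII grids for single-band rasters
and long-format CSV with a JSON header for NDVI cubes. Gap filling is
inverse-distance weighting over the k = 12 nearest valid cells with power
2 (neither value is standardized anywhere; both are arguments), and
resampling is single-pass nearest-neighbor — each raster carries a resample
counter so a pipeline can prove no raster was resampled twice.

## Known limitations

* EMD boundary handling (mirrored end extrema) still biases envelopes for
  very short series; decompositions of 22-point annual series should be
  read qualitatively beyond the first mode.
* The PLS-PM bootstrap uses a normal approximation for p-values rather than
  percentile intervals; with 200 resamples the difference is immaterial for
  the strong paths it is used on.
* The convolutional regressor is deliberately small; it is a working
  implementation of the documented architecture, not a tuned deep-learning
  stack, and it inherits no monotonicity guarantees — the scenario
  monotonicity test holds for the constructed monotone system, not in
  general.
* Natural-breaks classification on very large vectors (beyond ~10⁴ values)
  should subsample; the exact DP is quadratic in n.
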