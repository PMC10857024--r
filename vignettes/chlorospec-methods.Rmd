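---
title: "Methods: chlorophyll estimation from spectral and colour vegetation indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chlorophyll estimation from spectral and colour vegetation indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlorospec)
```

## The estimation problem

Leaf chlorophyll content is the central physiological readout in greenhouse
and soilless (aquaponic/hydroponic) lettuce production: it tracks nitrogen
status, stress and harvest quality. The reference measurements are destructive
(acetone extraction and spectrophotometry) or hand-held (SPAD-502
transmittance readings, unitless but linearly related to true chlorophyll
over the working range). Two non-contact proxies are cheaper and faster at
scale: narrow-band reflectance spectra from a field spectroradiometer
(350–2500 nm), summarised into *spectral vegetation indices* (SVIs), and
consumer RGB images of the plant, summarised into *colour vegetation indices*
(CVIs) after the leaf is segmented from its background.

`chlorospec` implements this estimation chain end to end: it regresses
SPAD readings on SVI and/or CVI feature sets with an automated random-search
model harness, evaluates with R² and RMSE on a held-out partition, and ships
a synthetic-data generator that reproduces the statistical structure the
chain assumes, so that every stage is testable without access to a measured
campaign.

## The synthetic leaf model

No raw spectra or images are distributed with the studies this pipeline
serves, so the generator is a first-class, tested module. Its reflectance
model is deliberately minimal rather than a radiative-transfer simulation:

* a smooth baseline `B(lambda)` — moderate visible reflectance
  (`baseline_visible`, default 0.50) rising through a logistic red edge
  (centre 705 nm, scale 18 nm) to a near-infrared plateau (`baseline_nir`,
  default 0.55);
* Gaussian chlorophyll absorption bands centred at 430, 460, 640 and 665 nm.
  Band depth saturates with true chlorophyll `chl` as
  `depth * chl / (chl + k)` with half-saturation `k = 25` SPAD-equivalent
  units, mirroring the saturating response of absorption features to pigment
  concentration. Bands attenuate the baseline **multiplicatively**
  (a product of `1 - depth_i` terms, Beer–Lambert-like), so green and red
  reflectance decrease *strictly* with chlorophyll but never reach zero —
  an additive combination would clip to zero at high chlorophyll and break
  the monotonicity that ratio indices rely on;
* fixed-depth water absorption bands at 1450 and 1940 nm;
* per-sample multiplicative/additive scatter (`1 + N(0, 0.04)`,
  `N(0, 0.008)`), applied before per-band instrument noise
  (`N(0, 0.004)`), then clipping to [0, 1]. The scatter is exactly the
  affine distortion the SNV transform removes, which links the generator to
  the preprocessing tests.

SPAD readings follow `spad = slope * chl + intercept + N(0, 1.2)` with unit
slope by default, so the response variable is in SPAD units throughout;
wet-chemistry mg/L values appear only in the calibration module. True
chlorophyll is drawn uniformly over [5, 60]; the four-way nutrient-treatment
structure of a real greenhouse trial is *not* modelled (a uniform draw spans
the same range without committing to unknown mixture weights).

The camera model is a boxcar integration of the spectrum over
B = [450, 495], G = [495, 570], R = [620, 700] nm, scaled to 8-bit counts —
the simplest model under which green-band CVIs carry chlorophyll information.
On top of it, each sample's channels receive `camera_noise_sd` (default 6
counts) of Gaussian noise representing shot-to-shot exposure and illumination
variation. This term matters structurally: broadband averaging *suppresses*
spectrometer noise, so without a camera-specific noise source the 3-channel
record would paradoxically be cleaner than the narrow-band record, and the
empirically universal ranking — fused features ≥ all-SVI ≥ all-CVI — could
not emerge. With the default noise levels the tuned model reaches a held-out
R² of roughly 0.95–0.99 on fused features and clearly lower values on
colour-only features, the regime reported for real campaigns of this kind.

Leaf images are rendered as an ellipse (20–60% of the frame) filled with the
sample colour on a soil-brown background, both with per-pixel noise, plus a
ground-truth mask — a verifiable fixture for the segmentation stage.

What passing tests on these data do **not** show: robustness to canopy
geometry, specular highlights, mixed pixels, illumination gradients,
detector-junction artefacts, or non-uniform chlorophyll distributions within
a leaf. The generator's contract is statistical structure, not photorealism.

## Preprocessing

`savitzky_golay()` smooths each spectrum with a local least-squares
polynomial (default window 11 points, order 2 — mild smoothing that
preserves the narrow 665 nm feature on a 1 nm grid). The convolution weights
are derived from the normal equations rather than tabulated; the classical
5-point quadratic weights (−3, 12, 17, 12, −3)/35 arise as a special case
and are pinned in the tests. Edges use a one-sided truncated-window fit (no
padding), so output length equals input length and polynomials of degree ≤
the fit order are reproduced *everywhere*, not only at interior points. The
filter requires a uniform grid and directs the caller to resample otherwise.

`snv()` standardises each spectrum to mean 0, sd 1 (sample sd, n−1). The
pipeline's convention is smoothing **then** SNV — the conventional
chemometric order, pinned by tests since scaling before smoothing would let
edge effects leak into the normalisation.

By default vegetation indices are computed from **raw** reflectance;
`run_config(use_preprocessed = TRUE)` switches the index stage onto
SG+SNV-transformed spectra. Ratio-type index values on SNV spectra are not
comparable to published raw-reflectance values (SNV output changes sign and
scale), which is why raw is the default.

Band lookup interpolates linearly between bracketing grid points (exact hits
return stored values): field spectroradiometer grids are coarser in the SWIR
than in the visible, so index wavelengths cannot be assumed to sit on the
grid, and nearest-neighbour lookup would introduce a grid-dependent bias.

## The index registries

Nineteen SVIs (NDVI, NDVI1, NDVI3D, VOG2, MSR1, SIPI, MDATT1, MCARI, GRVI,
PRI, VARI, VREI, SR, RVSI, BGI1, Lic2, PSRI, NPCI, CIgreen) and ten CVIs
(rn, gn, bn, GRRI, RBRI, GBRI, IKAW, NDI, WI, GLI) are registered centrally.
Three registry notes:

* **MCARI** is implemented as
  `[(R702 − R671) − 0.2 (R702 − R549)] · R702/R671`, with R549 as the green
  reference band — the form used throughout the MCARI literature; published
  tables sometimes drop the "R" from the 549 term.
* **VARI** uses the standard grouping `(R559 − R661)/(R559 + R661 − R488)`.
* **VOG2** and **VREI** are aliases of the same red-edge ratio `R740/R720`;
  both names are kept so per-index report tables can carry both rows.

Any denominator within 1e−12 of zero yields an explicit undefined marker
(`NA`), never an exception and never a silent zero. At feature-table
assembly, rows containing undefined values are dropped with a reported count
(default), or kept for the model pipelines' median imputer
(`na_action = "keep"`). Every formula is checked against an independently
hand-written oracle on 1000 random band tuples at 1e−12.

## SPAD ↔ wet-chemistry calibration

`arnon_total_chlorophyll()` returns exactly `20.2·A645 + 8.02·A663` (mg/L of
extract); conversion to per-mass leaf content (extraction mass/volume
scaling) is deliberately left to the caller, since reported values are
usually the equation's direct output. `fit_linear_calibration()` is OLS of
chemistry on SPAD; for this univariate fit `R² = r²` and `r` carries the
slope's sign, so a positive calibration with R² = 0.95 implies r = 0.9747
(0.975 to three decimals) — an analytic identity the tests pin.
`generate_absorbance_pair()` inverts the equation exactly (randomised split
between the two absorbance terms) for round-trip testing.

## Leaf segmentation

The deep encoder–decoder segmentation used in field studies is not
reproducible without its training data; `segment_leaf()` is a deterministic
classical segmenter with the identical downstream contract (a boolean leaf
mask): excess-green transform `2G − R − B`, 3×3 median filter
(edge-preserving denoising; at zero noise it leaves the mask pixel-exact,
unlike Gaussian smoothing), Otsu threshold, largest connected component,
hole filling. On the synthetic fixtures it reaches IoU ≥ 0.99 at zero noise
and mean IoU ≥ 0.90 across the default-noise suite, and is insensitive to
non-green background hue. One region per frame is assumed (single plant);
`mean_rgb()` averages channels over the mask, rounding the stored 8-bit
channels but computing normalised channels from unrounded means.

## The model-search harness

The automated-search protocol is re-implemented as a minimal, pinned
procedure rather than wrapped from an AutoML framework, so its behaviour is
fully testable: every pipeline is *median-impute → optional lognormal
feature transform → model*; candidates are drawn uniformly at random
(family, hyperparameters, transform flag) and scored by 5-fold
cross-validated MSE **on the training partition only**; the ranked list is
deterministic given the seed. Hyperparameter ranges bracket the defaults a
real search selects for this problem (extra-trees 100 trees/depth 6;
depth-wise boosting eta 0.1/depth 6/100 rounds; leaf-wise boosting lr
0.1/20 rounds/31 leaves/unlimited depth; random forest 482 trees/depth 25).
Bayesian optimisation is not implemented — the stated search procedure is
random search.

Backends: `ranger` for random forest and extra-trees
(`splitrule = "extratrees"`, one random split, no bagging);
`xgboost` for both gradient-boosted variants — depth-wise growth for the
XGB-style surface, histogram + loss-guided growth with a leaf cap and
`max_depth = 0` (no limit) for the LGBM-style surface. The contract is the
hyperparameter surface, not a specific binary.

Baselines: **PLSR** (via `mixOmics`, components chosen by inner 5-fold CV up
to min(10, p); predictions are computed from the extracted coefficients as
the exact linear form `Σ βᵢHᵢ + C`, which centred PLS regression reduces to,
and `coef()` exposes the βᵢ and C; a single feature degenerates to OLS);
**SVM** (radial kernel, standardised features); **BPNN** (single hidden
layer of 64 units, standardised inputs and response). `nnet` offers no
validation-based early stopping, so the network is regularised by weight
decay (1e−3, 200 iterations) instead — at these data sizes both mechanisms
serve the same purpose of preventing overfit.

The lognormal transform is applied to **features only** by default (whether
a response transform was intended is ambiguous in the protocol this
mirrors); the shift is derived from the training data so all shifted values
are ≥ 1, stored in the fitted pipeline, and predict-time values are floored
at 1e−9 after shifting.

## Evaluation

`rmse()` and `r_squared()` follow the standard definitions; R² on the test
partition uses the **test set's own mean** as baseline (so predicting that
mean scores exactly 0, and poor models can score negative). `model_report`
carries Rc²/RMSEc (calibration = training partition) and Rp²/RMSEp
(prediction = held-out partition); `experiment_report()` assembles one row
per feature set with paired Rp²/RMSEp columns per model family, refusing
duplicate (feature set, family) entries. The outer split is a seeded random
70/30 partition with `round(n·fraction)` (half-up) training rows — 3600
samples give the conventional 2520/1080.

## Reproducibility and problem sizes

One global seed fans out to per-stage seeds (`stage_seed()`, a stable hash
of stage name and global seed), so individual stages can be rerun in
isolation. End-to-end runs with tree/PLSR families are bit-reproducible;
all tree backends run single-threaded for determinism.

The package's standard benchmark — used by the test suite and
`scripts/acceptance.R` — is n = 600 samples, search budget 30, 5-fold inner
CV, five replicate seeds, three feature sets (fused, all-SVI, all-CVI).
These sizes give stable estimates of the feature-set ordering while keeping
a full run in the ten-minute range on one core. At this scale the fused and
all-SVI sets are nearly tied (the 10 colour columns add little beyond 19
spectral indices), which is why the ordering check carries a small sampling
slack (−0.01) on the mean margins.

## Known limitations

* The generator is phenomenological: no PROSPECT-class leaf optics, no
  canopy or illumination model, no treatment-group structure.
* The segmenter assumes one green plant on a non-green background; it will
  not separate overlapping plants or green-on-green scenes.
* CVIs are computed on 8-bit channel means; only WI's magnitude depends on
  that scale choice among the registered indices (the others are
  scale-invariant ratios).
* The printed accuracies of field campaigns (e.g. fused Rp² ≈ 0.98 on 3600
  measured spectra) are properties of their measured data; on synthetic
  data this package reproduces the qualitative regime and ordering, not
  those exact values.
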