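---
title: "One-class novelty detection for weed mapping: models, calibration and design choices"
author: "weednov authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-class novelty detection for weed mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weednov)
```

## The problem

Mapping an invasive weed such as *Silybum marianum* in high-resolution
multispectral imagery is awkward for ordinary two-class classifiers: the
surrounding vegetation is a heterogeneous mixture of species whose spectra
overlap the target's, and exhaustive ground truth for "everything that is
not the weed" is rarely available. One-class (novelty detection)
classification turns the problem around: a model of the *target class only*
is learnt from target pixels, and every pixel that deviates from that
description is assigned to "other vegetation". weednov implements four such
detectors behind one contract, together with the feature extraction,
calibration protocol and accuracy assessment needed to use and compare
them.

Each pixel is described by a 4-vector: green, red and near-infrared (NIR)
reflectance plus a texture band, the local variance of the NIR band in a
7 × 7 moving window. Texture is what separates the large, rough-canopied
target individuals from the smooth graminaceous background even where the
band reflectances overlap.

## The detectors and their decision rule

All four models expose `noveltyScores()` (a non-negative deviation score)
and `classifyFeatures()` (code 1 = target where score ≤ threshold, code
2 = other where score > threshold; the threshold point itself is a
target). The thresholds are calibrated the same way everywhere: sort the
training-target scores, take the order statistic at
`k = round(fraction × N)` and cut at the midpoint between the k-th and
(k+1)-th value (`fractionThreshold()`). With distinct scores this rejects
exactly `N − k` of the training targets, so the training rejection rate
equals the configured outlier fraction to within 1/N.

**SVDD / one-class SVM** (`fitSvdd()`): the minimal enclosing hypersphere
of the target data in the feature space induced by the Gaussian kernel
`K(x, z) = exp(−‖x − z‖²/σ²)`. The dual problem — maximise
`Σᵢ αᵢ K(xᵢ, xᵢ) − Σᵢⱼ αᵢ αⱼ K(xᵢ, xⱼ)` subject to `Σ αᵢ = 1`,
`0 ≤ αᵢ ≤ C` with `C = 1/(N ν)` — is solved by SMO-style pairwise
coordinate ascent: mass moves from the most-binding coefficient to the
least-binding one with the exact 1-D step, clipped to the box, until the
KKT gradient gap falls below tolerance. The score of a vector is its
squared kernel distance to the sphere centre. Defaults: σ = 2.5 on
standardized features, ν = 0.05. Two radii exist: the classical radius
read off boundary support vectors (kept in the model as
`boundaryRadiusSq`) and the order-statistic radius actually used as the
threshold; the latter makes the 5% training rejection exact and unifies
thresholding across detectors.

**One-class SOM** (`fitOcSom()` + `calibrateSom()`): an 8 × 8 rectangular
codebook grid trained by online Kohonen learning on target data; the score
of a vector is its quantization error, the squared distance to its best
matching unit (BMU, ties broken toward the lowest unit index). The
training schedule is conventional: Gaussian neighbourhood on the grid,
radius decaying exponentially `max(rows, cols)/2 → 0.5`, learning rate
`0.5 → 0.01`, 20 epochs, codebooks initialized from a seeded sample of
training rows. All schedule parameters are exposed as arguments. The
threshold accepts 95% of training targets by default.

**Autoencoder** (`fitAutoencoder()`): one hidden layer of 8 sigmoid units
with a linear read-out, trained by full-batch gradient descent on mean
squared reconstruction error; the score is `‖x − x̂‖²`. The linear output
layer is deliberate: features are standardized, so a sigmoid output could
never reproduce values outside (0, 1), and a single hidden layer yields a
principal-component-like subspace description in any case. Full-batch
descent was chosen over stochastic variants for exact reproducibility
given the seed; weights start at seeded uniform `[−0.5, 0.5]/√fan_in`.
The outlier fraction of the threshold is 5%, matching the SVM and SOM: no
separate figure is stated for this detector in the protocol the package
follows, and consistency across detectors keeps the comparison fair.

**One-class PCA** (`fitOcPca()`): the orthonormal basis of the leading
principal components of the (centred) target covariance; the score is the
squared reconstruction distance `‖(z − μ) − WWᵀ(z − μ)‖²`, valid in this
simplified form because `W` is orthonormal. The component count follows a
retained-variance fraction (default 0.95) or an explicit `nComponents`;
the threshold rejects 10% of training targets by default — the higher
figure reflects that the subspace description is the loosest of the four.
Centring is applied even though standardized features are already
near-zero mean, because the model is also usable on raw matrices.

## Calibration protocol

`runTraining()` reproduces the full protocol: assemble features, draw a
balanced calibration sample (1434 pixels per class by default, 2868 in
total), split it 70/30 stratified within each class (yielding exactly
2008 training and 860 test pixels at the default sizes, with half-up
rounding per class), standardize all features by the mean and standard
deviation of the *target-class training rows*, and fit the detector on
those target rows only. The "other" class never reaches a detector — it
exists solely to score the held-out 30%. Standardization matters because
the RBF spread and every fraction threshold are scale-sensitive; the map
is stored in each model and re-applied at prediction time, and feature
tables standardized under a different map are refused.

## The scene simulator

No imagery ships with the package; `simulateScene()` generates labelled
study conditions with the statistical structure the analysis assumes:

* **Patch geometry** — white noise smoothed with a Gaussian of length
  `patchScale` (10 px default) and thresholded at the quantile giving
  `patchCoverage` (0.3 default). One parameter controls patch size, a
  second controls coverage exactly up to ties.
* **Spectra** — class means target (0.10, 0.09, 0.55) and background
  (0.09, 0.10, 0.42) with smooth within-class variability of sd 0.02.
  These are synthetic values chosen to mimic the qualitative field
  pattern — visible bands nearly identical between classes, NIR partially
  separated — not field measurements.
* **Texture** — pixel-scale Gaussian noise with sd 0.08 (target) versus
  0.005 (background). The order-of-magnitude contrast encodes the rough
  target canopy against the smooth background and is what the 7 × 7 local
  variance band picks up.
* **Correlation structure** — each class draws *one* smooth field and
  *one* pixel-noise field, shared across the three bands and scaled by the
  per-band spread and the class texture amplitude. Canopy vigour, shading
  and roughness move a plant's whole spectral signature together; modelling
  the fields per band instead would make the standardized target class
  nearly isotropic, which both misrepresents real canopies and removes the
  low-dimensional structure that any subspace description feeds on.
* **Determinism** — every stage draws from its own sub-stream derived from
  the scene seed, so changing one parameter does not reshuffle unrelated
  noise, and identical configurations yield bit-identical scenes.

What the simulator does **not** emulate: mixed pixels at patch borders,
illumination gradients and shadows, sensor noise correlated along scan
lines, seasonal senescence gradients, and the long-tailed species mixture
of a real field. Passing the end-to-end benchmark therefore demonstrates
that the detectors, calibration and scoring machinery work as specified
under controlled conditions with realistic spectral overlap and texture
contrast — not that any particular accuracy will be achieved on real
imagery.

## Numerical choices

* Local variance uses the population (1/n) estimator, matching the usual
  raster texture operator, with reflect padding at edges (the repeated
  reflection also covers windows and smoothing kernels larger than the
  grid). Bands are shifted by their global mean before the moving sums, so
  flat regions give exactly zero instead of catastrophic cancellation
  residue. Nodata pixels are excluded from window statistics.
* Scene bands live on the 2⁻³² sample grid of the 32-bit TIFF encoding the
  I/O layer uses, making `readScene(writeScene(x))` bit-exact; the nodata
  mask travels in a JSON sidecar (run-length encoded) because the TIFF
  layer has no NaN-capable float path.
* `fractionThreshold()` and the split arithmetic round half-up,
  deterministic at .5 ties.
* The SVDD stopping rule is a KKT gradient gap below `tol` (default 1e-8);
  support vectors are coefficients above 1e-9. Model files store doubles
  at 17 significant digits so the JSON round trip is exact.
* Accuracy metrics are kept at full precision and rounded half-up to two
  decimals only in `formatMetrics()`. Metrics with zero denominators are
  `NA` (undefined), never zero. The commission error of a class is defined
  over the actual total of the *opposite* class — the convention under
  which a published 2 × 2 table's omission and commission percentages are
  mutually consistent.
* The free-parameter count of the PCA description is recorded as `d · M`
  in model metadata only; it plays no computational role.

## Problem sizes

The test-suite and acceptance benchmarks run on 128 × 128-pixel scenes
(16 384 pixels, about 4 900 of them target) with the full 2 × 1434
calibration protocol, five scene seeds for the stochastic end-to-end
checks, and one 886 × 884 scene (783 224 pixels — full-mosaic scale) for
whole-scene classification with all four detectors. These sizes exercise
every code path at realistic calibration scale while keeping a complete
run in tens of seconds on one CPU.

## Known limitations

* The SVDD solver is exact but dense: memory is O(N²) in training-target
  count, comfortable at the protocol's ~1000 training targets, unsuitable
  beyond ~20 000 without chunked kernels.
* SOM training is online and order-dependent by construction;
  reproducibility comes from seeding, not from order-invariance.
* The autoencoder uses plain gradient descent; very aggressive learning
  rates diverge (that error suggests the remedy), and deep or convolutional
  variants are out of scope.
* The pipeline carries pixel size but no coordinate reference system:
  outputs are rasters aligned with their inputs, not georeferenced
  products.

## A worked run

```{r example, eval = FALSE}
cfg <- sceneConfig(width = 128, height = 128, seed = 1)
sim <- simulateScene(cfg)
bench <- runBenchmark(sim$scene, sim$labels, perClass = 1434, seed = 1)
bench$summary
```

The summary holds one row per detector with overall, user's and producer's
accuracy on the 860 held-out pixels and the realized training rejection
rate; `scripts/acceptance.R` in the repository reruns this benchmark over
five seeds alongside the published-table arithmetic.
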