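---
title: "Kernel-based seed viability scoring from SWIR hyperspectral images"
author: "hyperseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-based seed viability scoring from SWIR hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperseed)
```

## The problem and the model

Viable and nonviable seeds of the same lot can be visually identical, yet
differ subtly in composition: aging hydrolyzes proteins, lipids and starch,
which shifts near-infrared absorption at characteristic C–H/O–H/N–H overtone
bands. A line-scan SWIR camera records, for every pixel of a plate of seeds,
a reflectance spectrum over ~1000–2500 nm. The analysis problem has two
layers:

1. a *pixel-level* model scoring each seed pixel's spectrum for viability,
   and
2. a *seed-level* (kernel) decision aggregating those noisy pixel calls into
   one call per seed.

The pixel model is PLS-DA: NIPALS PLS1 regression of a 0/1 dummy (viable = 1)
on the mean-centered pixel spectra, classified by `score > 0.5` (strict).
PLS is the right tool because bands vastly outnumber informative directions
and are heavily collinear. The seed rule computes each kernel's *detection
rate* — the percentage of its pixels scoring above 0.5 — and declares the
seed viable when the rate reaches a threshold (inclusive). The threshold is
not fixed at 50%: it is swept over the full 0–100 range on the calibration
seeds and set to the value minimizing false positives plus false negatives
(the *optimum detection rate*). Pixel errors are roughly independent within
a seed, so a seed's detection rate concentrates tightly around its class
mean; even an 85%-accurate pixel model yields nearly disjoint rate
distributions and near-perfect seed classification. That aggregation step,
not the pixel model, is the load-bearing idea.

### Assumptions

* Each seed is a single connected blob, spatially separated from its
  neighbors (no touching-kernel splitting is attempted).
* Ground-truth classes are organized by plate rows (the layout of the
  imaging protocol), so truth can be attached geometrically.
* Pixel scores within a seed are exchangeable: the detection rate is a
  sufficient summary (no spatial pattern inside the kernel is used).
* Viable is the positive class everywhere: a false positive is a nonviable
  seed shipped as viable, the costlier error in seed commerce.

## Pipeline stages and their parameters

| stage | parameter | default | meaning |
|---|---|---|---|
| calibration | `floorGuard` | 1e-9 | floor for white−dark, guards dead detector pixels |
| crop | `cropLo`, `cropHi` | 1000, 1800 nm | modeling window; bands above 1800 nm carry mostly detector noise |
| mask | `maskBandNm` | 1300 nm | single band with strong seed/background contrast |
| mask | `maskThreshold` | scene-derived | contrast midpoint for synthetic scenes; must be set per real dataset |
| mask | `seedsAbove` | TRUE | polarity; contrast direction depends on plate material |
| labeling | `minSeedPixels` | 20 | removes specular debris; seeds are compact blobs |
| pretreatment | `method` | `snv` | per-spectrum transform (raw/snv/max/mean/range/smoothing) |
| smoothing | `window`, `polyorder` | 11, 2 | Savitzky–Golay, the conventional spectroscopy default |
| split | `calibFraction` | 0.75 | seed-level stratified split |
| CV | `cvFolds` | 10 | seed-grouped folds for RMSECV |
| CV | `maxLV` | 15 | largest candidate latent-variable count |
| VIP | `threshold` | 1 | scores above one mark informative bands |
| VIP | `minSeparation` | 2 bands | adjacent bands are redundant; keeps peaks apart |
| decision | `useOptimal` | TRUE | ROC-learned rate vs a fixed rate (e.g. 50%) |

Wavelengths are always in nanometres; detection rates and accuracies in
percent; reflectance is dimensionless.

## Design choices where the design was open

* **Boundary conventions.** The pixel rule is strict (`score > 0.5`; a score
  of exactly 0.5 is nonviable) while the seed rule is inclusive
  (`rate >= threshold` is viable). Both directions are fixed and tested; the
  asymmetry mirrors how the two rules are conventionally written.
* **Optimum-rate tie-breaking.** Among thresholds minimizing FP + FN, ties
  resolve first to fewer FP (discarding a viable seed is cheaper than
  shipping a nonviable one), then to the larger threshold. With perfectly
  separated calibration rates this lands on the smallest viable calibration
  rate — the most FP-averse perfect threshold. It is deliberately
  conservative toward the nonviable class; a validation viable seed can
  occasionally fall just below it, which is visible in the aggregate checks
  (18–20 of 20 synthetic replicates reach ≥95% seed accuracy in both
  classes).
* **ROC threshold grid.** All integer percents 0–100 plus every observed
  rate, plus one cut above 100 to close the curve at sensitivity 0. The
  observed rates make every distinct confusion matrix realizable, so the
  trapezoidal AUC equals the Mann–Whitney pair-counting statistic exactly
  (an identity the tests verify to 1e-12); the integer grid alone would
  change AUC only negligibly.
* **Split and CV granularity.** Splits and folds are formed at the *seed*
  level, stratified by class. Pixel-level splitting leaks: adjacent pixels
  of one seed are nearly duplicates, and seed-level evaluation counts (n =
  hundreds of seeds, not 10⁵ pixels) show the decision unit is the seed.
  Pixel-level folds remain available (`bySeed = FALSE`).
* **RMSECV minimum, first occurrence.** The curve typically flattens; on
  ties the smallest A wins (parsimony). The default of 10 folds keeps CV at
  desk scale; the fold count is configurable for larger studies.
* **Baseline correction operator.** Line-scan drift produces striped band
  images. No canonical operator exists for this; the package subtracts, per
  scan line and band, the median of that line's *background* pixels — a
  robust estimate available in every line because seeds never fill a line.
  Lines without background pixels fall back to offset 0 with a warning. The
  background/foreground split reuses the 1300 nm mask computed on the
  uncorrected cube (correction shifts levels, so the mask must be taken
  first).
* **Smoothing operator.** "Smoothing" is implemented as Savitzky–Golay
  (window 11, order 2) rather than a moving average: it is the spectroscopy
  default, preserves polynomial band shapes exactly, and both parameters are
  exposed.
* **SNV convention.** Sample (n−1) standard deviation, the dominant
  chemometrics convention.
* **Row assignment.** Seed centroids are binned into `length(layout)` equal
  intervals of the centroid range — no clustering step that could silently
  mis-order rows; centroids within a guard margin (5% of a bin width) of a
  boundary are flagged unknown rather than guessed.
* **Band lookup.** `bandImage()` takes the nearest band center; equidistant
  ties go to the lower wavelength, a documented deterministic rule.
* **White/dark frames.** Accepted either as full cubes or as single
  reference lines (`samples x bands`) broadcast across scan lines, since
  line-scan systems record reference lines. Whether a real system averaged
  frames or lines is immaterial to the arithmetic.
* **No reflectance clipping.** Calibrated values may slightly leave [0, 1]
  under noise; clipping would distort SNV statistics downstream.

## The synthetic generator

`renderScene()` emulates what the pipeline's corrections target, with known
ground truth:

* seeds as filled disks on a spaced grid, rasterized into an integer label
  map; classes assigned per grid row (alternating by default);
* a smooth soybean-like base spectrum (reflectance peaks near 1300/1600 nm,
  valleys near 1200/1400 nm, a water band past 1900 nm);
* the class difference as additive Gaussian bumps (default amplitude 0.014,
  sd 20 nm) on the *nonviable* class at 1165, 1335 and 1405 nm — the
  direction is arbitrary and documented; what matters is that the two class
  means differ only near known bands, so VIP selection has a recoverable
  target;
* per-pixel lognormal multiplicative scatter (sd 0.08), per-scan-line
  additive drift (sd 0.012) affecting background too, and i.i.d. detector
  noise (sd 0.025) — exactly the distortions SNV and baseline correction
  remove, making pretreatment effects observable in tests;
* raw counts and white/dark frames constructed so calibration recovers the
  reflectance scene exactly (bit-level closure when all noise is off).

The default plate (`defaultPaperLikeScene()`) is a 10 × 10 grid (100 seeds,
50 per class) with 256 bands over 1000–2500 nm, echoing a 256-spectral-pixel
line-scan detector. The noise/effect-size defaults were calibrated once so
that the default pipeline's pixel-level validation accuracy falls in the
80–90% band — the regime in which seed-level aggregation visibly rescues the
classifier — and then frozen.

What the generator does **not** emulate: realistic soybean radiometry,
optical point-spread, touching or elliptical seeds, spatially correlated
detector noise, wavelength miscalibration. Passing tests therefore
demonstrate the *algorithmic* correctness and the aggregation claim under
controlled violations, not instrument-grade performance on real seeds.

## Numerical notes

* NIPALS weights are unit-normalized; deflation is X-side only (PLS1). When
  residual covariance is exhausted (`‖Xᵀy‖ < 1e-12`) the component count is
  truncated with a warning (silently capped inside CV folds, where it is
  routine at large A).
* `beta = W (PᵀW)⁻¹ q` collapses the factors; factor and beta prediction
  routes agree to 1e-8 on training data, and at full rank the fit equals the
  normal-equations least-squares solution (both tested).
* VIP scores satisfy `Σ_j VIP_j² = p` to 1e-10 by construction; this is
  asserted as a class invariant.
* The ENVI raster is stored as little-endian float32 by default (float64
  available); the wavelength axis is written at full precision in the ASCII
  header. Round-trips are exact for the stored dtype.
* Degenerate spectra under pretreatment (e.g. constant under SNV) are
  collected into one report and left untransformed rather than aborting a
  whole cube.

## Problem sizes

The shipped tests run plates between 2 × 2 and 10 × 10 seeds (up to 100
seeds, ~4 900 seed pixels, 256 bands), with 10-fold seed-grouped CV up to 15
latent variables, and 20-replicate simulation loops for the aggregate
claims; these sizes were chosen as the smallest at which the seed-level
claims are statistically meaningful. All are package defaults or test
parameters and scale up by changing `SceneSpec` fields.

## Known limitations

* The optimum detection rate is learned from calibration seeds only; on
  small plates its FP-averse tie-breaking can sit at the edge of the viable
  rate distribution (see above).
* 100-seed plates imply small validation sets (~24 seeds); per-class seed
  accuracies are correspondingly coarse (steps of ~8%).
* Segmentation is a single-band threshold; scenes whose background/seed
  contrast reverses across the plate need per-dataset threshold and polarity
  choices.
* The ROC is computed on seed-level detection rates, so AUC values from few
  seeds are step-function coarse.
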