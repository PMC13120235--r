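---
title: "Variety screening in blended plant products: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variety screening in blended plant products: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blendspec)
```

## The problem

A blended plant product (the motivating case is tobacco) is a mixture of
botanical varieties, and authenticity checking asks two questions per
targeted variety: *is it present?* and *at what proportion?* Varieties of
one plant species have nearly indistinguishable infrared spectra, so both
questions require supervised multivariate calibration rather than library
matching. `blendspec` answers them with one binary PLS-DA classifier and
one PLS1 regression per variety, built from a designed set of blend
spectra. This vignette explains the models, the tunable parameters, the
synthetic data the package is validated on, and the design decisions made
where the procedure was genuinely open.

## Models

**NIPALS PLS1.** Spectra are mean-centered and components are extracted
one at a time: weights proportional to the covariance of the residual
spectra with the residual response, scores by projection, then rank-one
deflation of both. Prediction uses the collapsed coefficient vector
`b = W (P'W)⁻¹ q` plus an intercept, which agrees with running new samples
through the score recursion (a property the test suite asserts to 1e-10).
Centering is always performed inside the fit, for every pre-treatment —
autoscaled data are simply centered twice, which is idempotent. If the
response is exhausted before the requested number of components (exactly
rank-deficient data), extraction stops early and the model carries an
`early_stop` flag instead of propagating NaNs.

**PLS-DA.** Classes are coded 0/1 and the coded response is fitted as
above; a sample is positive when its predicted score strictly exceeds 0.5.
The coding and threshold are a documented convention (the most common
one, symmetric under class swap), not something the procedure prescribes;
no probability calibration is applied.

**Why binary models per variety?** A set of binary models can be extended
with a new variety without refitting everything, tends to predict better
in complex matrices, and is cheap enough for portable instruments. PLS2 or
multiclass alternatives are deliberately out of scope.

## Pre-treatments

Six recipes are swept for every model: `autoscale`, `snv`, `d1`, `d2`,
`snv_d1`, `snv_d2`.

- **SNV** standardizes each spectrum to mean 0 / SD 1 (n−1 denominator),
  removing per-sample multiplicative scatter and offset.
- **Savitzky–Golay derivatives** (2nd-order polynomial, window 17
  channels) remove additive baselines (d1: constant + slope via d2) and
  sharpen band structure. Coefficients are scaled per cm⁻¹, so results do
  not depend on the grid spacing. Edge channels without a full window are
  truncated — a window of 17 costs 16 channels — rather than extrapolated,
  avoiding edge artefacts.
- **Autoscaling** centers and scales each channel with *training*
  statistics; zero-variance training channels map to 0 rather than
  erroring, since a derivative-flattened region carries no information.
- The combined recipes apply SNV first, then the derivative.

SNV and derivatives are sample-local and therefore leak-free by
construction; autoscaling is the only statistics-bearing step and is
re-fitted on the training part of every CV fold.

## Splitting and validation

**Duplex.** The external test set is chosen deterministically in the raw
spectral space: the most distant pair of unassigned samples goes to
training, the next pair to test, alternating until the test set is full;
all remaining samples train. Distance ties prefer the lexicographically
smaller index pair; an odd final slot takes the pair member farther from
the existing test set. The default test fraction is 20% (`round(0.2 n)`),
and distances are always computed on un-pre-treated spectra, once per
dataset, shared by all six recipes.

**Cross-validation.** 10-fold CV on the training set selects the component
count: folds come from a seeded shuffle, stratified for classification so
each fold's positive count is within one of proportionality (at ~50
training samples unstratified folds can go single-class). RMSECV is pooled
over all held-out predictions; the minimum selects the component count,
with ties (within 1e-12) resolved toward the simpler model. `max_lv`
defaults to 15, capped at `n_train − ⌈n_train/folds⌉ − 1` so every fold
can support the largest model.

**Recipe selection** is primarily by the external test criterion (RMSEP,
or test CCR), with ties — equality after rounding to 4 decimals — broken
by the CV criterion and then by fewer components. Selecting on the test
set re-uses it, so the reported test figures are optimistic; that is the
replicated procedure, kept deliberately, and an untouched validation layer
can always be added on top by the user.

**Metrics.** RPD (SD of test references / RMSEP, n−1 convention
throughout) and RER (reference range / RMSEP) are reported with the
conventional bands (RPD: <1.5 poor, 1.5–2.0 rough screening, 2.0–2.5
approximate, 2.5–3.0 good, >3.0 excellent; RER: <5 poor, 5–10 acceptable,
>10 excellent). Ratios with zero denominators are NaN with a warning,
never silently 0.

## The synthetic study set

No measured spectra are distributable with the package, so the generator
emulates the study conditions end to end and every downstream stage is
validated on it.

- **Endmembers:** each variety's spectrum is a sum of 30 shared Gaussian
  bands plus 8 variety-specific bands scaled by `similarity_delta = 0.15`,
  on the NIR grid (4000–10000 cm⁻¹, step 8; 751 channels) or the MID-IR
  fingerprint grid (650–1998 cm⁻¹, step 4; 338 channels — the last full
  step below 2000). Band centers are uniform on the grid, widths uniform
  in 20–150 cm⁻¹. The default delta makes all pairwise endmember
  correlations exceed 0.99 — "varieties of the same plant".
- **Design:** all 63 nonempty equal-proportion subsets of the six
  varieties (pures, 15 binary, 20 ternary, 15 quaternary, 6 quinary, 1
  senary at 100/6 ≈ 16.7% each) plus 24 triturations (1, 2, 5, 8% of each
  variety in the equal quinary background, e.g. 8% + 5 × 18.4%), 87
  samples in total. The per-variety regression set is the 32 subset rows
  containing the variety plus its 4 triturations: 36 samples spanning
  1–100%.
- **Measurement model:** observed = `exp(g) · clean + b₀ + b₁·ν̃ + ε`,
  with per-sample `g ~ N(0, 0.05²)` (log-normal scatter, what SNV
  removes), per-sample affine baseline `b₀, b₁ ~ N(0, 0.01²)` on the
  grid scaled to [0, 1] (what derivatives remove), and white noise
  `ε ~ N(0, 0.001²)` per channel. Clean mixing is linear Beer–Lambert in
  absorbance, which makes exact recovery a testable limit: with all sigmas
  zero, PLS with ≥ 5 components reproduces proportions to numerical
  precision, and the test suite asserts it.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: batch-to-batch natural variation of a variety,
non-linear detector and particle-size effects, water-vapour/CO₂ bands,
additives and flavourings, and realistic (non-Gaussian) band shapes.
Results on the synthetic set demonstrate that the pipeline machinery is
correct and that the procedure recovers what its own model family can
express, not that any real product will classify at these rates.

## Numerical choices and degenerate inputs

- Seeds are mandatory everywhere randomness exists (generator, folds,
  unknown-sample compositions); all generation and modelling is
  bit-reproducible given the seed, and RNG state is restored afterwards.
- SD uses the n−1 denominator in SNV, autoscaling and RPD alike.
- Constant spectra are an error in SNV (naming the sample); constant
  channels are tolerated and zeroed under autoscaling; zero-variance
  responses are an error in `pls1_fit`.
- A classification fold whose training part is single-class triggers one
  re-seeded reassignment, then an error.
- The LOD rule is monotone-tail: the smallest level from which all higher
  levels are positive; an isolated positive below it is reported in the
  flags but does not lower the LOD. Under the default synthetic
  conditions most varieties come out above the tested range (">8%"):
  with training positives at ≥ 16.7% and a 0.5 threshold, low triturations
  score below the decision line. The LOD machinery is exercised by the
  flags themselves, not by any particular value.
- Proportions are stored exactly (100/3, 100/6) and rounded to one
  decimal only for display; CSVs keep full double precision (17
  significant digits) and round-trip bit-exactly.

## Problem sizes

The shipped analysis and the acceptance script run the full 87-sample NIR
design with all six varieties, six recipes, 10-fold CV and `max_lv` 15 —
about 800 NIPALS fits — in under a minute on one CPU. The test suite uses
the same full design for end-to-end checks and much smaller instances
(n = 12–20) for oracle-equivalence tests.

## Known limitations

- The external-test-based recipe selection is optimistic by construction
  (see above).
- The duplex odd-slot and tie rules are conventions; other chemometrics
  software may differ in those corners.
- The PLS-DA threshold is fixed at 0.5 with 0/1 coding; heavily unbalanced
  designs would warrant a calibrated threshold.
- Screening extrapolates: commercial-like blends have proportion patterns
  (0.5–40%) the equal-proportion calibration never saw, and estimates for
  qualitative negatives are deliberately never produced.
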