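---
title: "Methods: hyperspectral seed-variety identification with spectrograin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral seed-variety identification with spectrograin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Seed varieties of a crop such as soybean are hard to tell apart by eye, yet
variety purity matters for yield, processing and seed markets. Visible/
near-infrared hyperspectral imaging offers a nondestructive route: each
seed's mean reflectance spectrum over ~400-1000 nm carries a chemical
fingerprint of its coat and interior. The statistical task is a
ten-or-so-class classification from a few hundred correlated spectral
bands, and the practical question is less "which classifier?" than "which
*combination* of spectral pretreatment, wavelength/feature extraction and
classifier?". `spectrograin` implements that full combination study as a
reusable pipeline:

1. **Calibration and I/O** — panel-based reflectance conversion
   `R = DN / DN_panel * R_panel`, ROI mean extraction from ENVI cubes,
   front/back averaging, and a flat CSV spectra-table format.
2. **Six pretreatments** — Savitzky-Golay smoothing (SG), first derivative
   (FD), standard normal variate (SNV), FFT low-pass filtering, Hilbert
   transform (HT), multiplicative scatter correction (MSC).
3. **Three feature extractors** — competitive adaptive reweighted sampling
   (CARS), the successive projections algorithm (SPA), and Kaiser-rule PCA,
   all backed by a PLS-DA/RMSECV engine.
4. **Five classifiers** — kernel-density naive Bayes, quadratic-kernel SVM,
   10-NN, a random-subspace LDA ensemble, and a single-hidden-layer neural
   network.
5. **The benchmark** — all 6 x 3 x 5 = 90 combinations on one shared
   stratified 3:1 split with leakage-safe 5-fold cross-validation.

Because the original images behind this kind of study are rarely deposited,
the package ships a synthetic spectra generator that reproduces the
*statistical structure* such data exhibit, so that every stage is testable
end to end.

## The synthetic generator: what it emulates and what it does not

A generated spectrum is

```
reflectance = gain * (template(lambda) + class_effect(lambda)) + offset + noise(lambda)
```

clipped to [0, 1.5] (reflectance calibrated against a gray panel can exceed
1). The pieces:

* **Template.** A fixed sum of Gaussian bumps whose defaults produce local
  reflectance maxima near 638 and 702 nm, a local minimum near 675 nm (the
  red-edge structure typical of yellow-coated seeds) and a broad
  near-infrared plateau. The bump amplitudes are free generator parameters:
  published curves pin the shape, not absolute values, so the defaults were
  chosen once to land the peaks on a 128-band grid and give reflectance in
  the 0.2-0.55 range.
* **Class effects.** Variety differences are smooth Gaussian bumps
  (sd 7.5 nm, i.e. full width about 15 nm — wide enough that wavelength
  selection is a non-degenerate task, not a single-band lookup), confined to
  the 638-660 nm and 700-980 nm windows where real varieties differ, and
  scaled by `class_separation`. The bumps are hard-truncated at the window
  edges so that between-class variance outside the windows is exactly zero —
  a property the selection tests rely on. Tests can plant bumps at known
  wavelengths (`class_bump_centers`) with chosen per-class amplitudes,
  which is how the CARS-recovery and trait-correlation oracles are built.
* **Scatter.** A per-sample multiplicative gain `1 + N(0, scatter_gain_sd)`
  and additive offset emulate the uneven particle-surface scattering that
  SNV and MSC exist to remove; this is what makes the "MSC/SNV win under
  scatter" benchmark property testable.
* **Noise.** Additive Gaussian noise with sd
  `noise_sd_base + noise_sd_edge * ramp(lambda)`, where the ramp rises
  linearly from 900 nm to the grid maximum — detector noise in these
  instruments grows toward 1000 nm, and a ramp avoids a discontinuity.

Defaults are 10 classes x 120 samples on 128 bands over 373-1043 nm,
matching the design of a realistic variety study. Within-variety variance
is not published for such studies, so the noise and scatter defaults
(`scatter_gain_sd = 0.05`, `scatter_offset_sd = 0.02`,
`noise_sd_base = 0.004`, `noise_sd_edge = 0.01`,
`class_separation = 0.03`) were chosen once for testability: strong enough
that the classification task is non-trivial, weak enough that scatter
correction plus a good classifier can approach perfect accuracy. Passing
tests on these data show the pipeline's *mechanics and contracts* are
right; they do not certify accuracy figures on any real instrument, where
wavelength-correlated chemistry, instrument drift and segmentation error
add structure the generator does not model. The generator also works at
the per-seed mean-spectrum level only; it does not simulate 2-D seed
images or imaging optics.

## Pretreatments: conventions and edge cases

All six map an `n x p` spectrum set to one of identical shape on the same
wavelength grid.

* **SG.** The conventional window of "8 points" found in chemometric
  protocols cannot be centered; a centered window must be odd. The default
  is therefore 9 points with polynomial order 2, and even windows are
  rejected with an explicit error. Edge bands are refitted with truncated
  asymmetric windows of the same order rather than shortening the output.
* **FD.** Central differences over wavelength for interior bands; the two
  endpoints use one-sided two-point differences to preserve shape.
* **SNV.** Per-spectrum centering/scaling with the `p - 1` denominator. A
  constant spectrum has no defined SNV and raises an error naming the
  sample.
* **MSC.** The reference is the columnwise mean spectrum. By default it is
  fitted on the training partition only and applied to held-out data
  (leakage-safe); `paper_mode` in the benchmark computes it over all
  samples, the classical full-data variant. Correction is
  `(x - beta) / alpha` from the OLS fit `x = alpha * ref + beta`.
* **FFT low-pass.** Brick-wall zeroing of DFT bins above the cutoff. The
  cutoff convention is normalized frequency in cycles per band interval
  (Nyquist = 0.5); with `cutoff = 0.125` this keeps the lowest quarter of
  the spectrum. Where a protocol states "cutoff 0.125" without a
  convention, this is the common reading; it is documented and
  configurable. The filter is a projection (idempotent), which the tests
  assert.
* **HT.** Output is the Hilbert transform itself (imaginary part of the
  analytic signal) of the mean-removed spectrum — a pure +/-90 degree phase
  shift with amplitudes unchanged, not an envelope. The DC bin has no
  defined phase shift (hence the mean removal) and the Nyquist bin no
  defined sign, so both are zeroed; the involution `H(H(x)) = -x`
  consequently holds exactly on zero-mean signals without Nyquist content,
  which is how it is tested (odd band counts).

## The selection engine

**PLS-DA / RMSECV.** Labels are one-hot coded and the indicator matrix
regressed on column-centered spectra by PLS2. Each latent component is
computed exactly as the dominant singular pair of the deflated
cross-covariance matrix — the fixed point the classical NIPALS iteration
converges to — which makes fits deterministic and fast without an inner
iteration tolerance. RMSECV pools squared CV residuals over all samples
and indicator columns under stratified k-fold CV (a fold missing a class
is an error, not a silent degradation). Band importance is the row-wise
Euclidean norm of the band x class coefficient matrix.

**CARS.** Each of `n_runs = 50` sampling runs draws a stratified 80%
calibration subset, fits PLS on the retained bands, and keeps the top
bands by coefficient magnitude down to the enforced exponentially
decreasing schedule `r(i) = a e^{-k i}` calibrated so `r(1) = 1` and
`r(n_runs) = 2/p`; the kept set is then resampled with probability
proportional to coefficient magnitude, without replacement, at the same
count — with this formulation the retained counts follow the schedule
exactly (run 1 retains all `p` bands, the final run 2), and run-to-run
stochasticity enters through the calibration subsampling. The RMSECV of
every run's retained set is evaluated on the full data with a fixed fold
assignment, and the set from the first-minimum run wins. The PLS component
count is chosen once per invocation (inner-CV argmin over 1..10 on the
full band set) and reused across runs for cost control. Selected-band
counts are data- and seed-dependent by nature; published per-pretreatment
counts from any one study are context, not reproducible targets.

**SPA.** From every candidate starting band a chain grows by successive
projections: the next band maximizes the norm of its column's projection
onto the orthogonal complement of the chosen columns, so duplicated or
collinear bands can never be co-selected; a chain truncates (without
error) if the residual space is exhausted. Every chain prefix is scored by
stratified 5-fold CV RMSE of an ordinary least-squares indicator fit —
computed incrementally from one Gram-Schmidt pass per chain and fold, so
all prefix sizes cost one decomposition. The selected subset is the
smallest prefix whose RMSE is within `1.01 x` the global minimum: the RMSE
curve flattens once the informative bands are in, and the plateau rule
("almost unchanged") picks the knee rather than the strict argmin. For
CARS, `best_index` is the trace argmin (first under ties); for SPA it is
the plateau choice — the two operations' own rules take precedence over a
single shared convention.

**PCA.** Bands are standardized and the correlation matrix
eigendecomposed; components with eigenvalue > 1 are retained (Kaiser rule
— below 1, a component carries less variance than one original
standardized band; the rule is only meaningful on the correlation scale,
which is why standardization is not optional here), with a floor of one
component. Zero-variance bands are dropped with a warning and recorded in
the model so `pca_apply` stays consistent.

## Classifiers

All five sit behind one `fit_predict(spec, train_x, train_y, test_x)`
contract; features are standardized with training statistics for SVM, KNN
and ANN. Engine choices where the conventional parameter tables are
silent:

* **bayes** — naive Bayes with a per-class, per-feature Gaussian kernel
  density estimate, bandwidth by the normal-reference rule (with a small
  floor against near-constant features). This matches a "Gaussian kernel"
  naive Bayes without further guidance.
* **svm** — `e1071::svm`, polynomial kernel of degree 2 with `coef0 = 1`,
  box constraint 1, libsvm's native one-vs-one multiclass voting
  (including its internal tie handling).
* **knn** — written in-package because the required tie behavior is part
  of the contract: all neighbors tied with the 10th distance are included,
  and class-vote ties break by the smallest mean neighbor distance, then
  class order. (The classical `class::knn` breaks vote ties at random,
  which would violate the determinism guarantee.)
* **el** — a random subspace ensemble: 30 LDA base learners, each on a
  seeded random draw of `min(40, p)` features, combined by majority vote
  with ties broken by summed posterior. The conventional ensemble
  "learning rate" parameter is recorded but inert under subspace voting.
  Base learners whose subspace is degenerate for LDA are skipped.
* **ann** — `nnet::nnet`: one hidden layer of 10 units, softmax output,
  at most 500 epochs, weight decay `1e-4`, seeded initialization.
  Scaled-conjugate-gradient training with a validation-split early stop is
  the MATLAB-style default for such networks; no installed R
  implementation provides SCG, and `nnet`'s quasi-Newton optimizer with a
  small weight decay plays the same regularizing role. This is the
  package's engine choice, documented rather than hidden.

`cross_validate` performs stratified k-fold CV in which every sample is
predicted exactly once by a model not trained on it; the pooled
out-of-fold confusion matrix (rows = truth) and its trace give the CV
accuracy.

## The benchmark grid and its leakage discipline

`run_grid` draws one stratified 3:1 split (per class, `ceiling(3n/4)` to
train) shared by all triples so cells are comparable. For each triple the
pretreatment is fitted on the training partition (MSC is the stateful
one), the selector on the pretreated training data, the classifier on the
selected training features. The reported CV accuracy is computed *within
the training partition*, re-fitting pretreatment and selection on each
fold's training part — the test partition stays untouched and no fold sees
its own statistics. Selections are cached per (pretreatment, selector
[, fold]) since they do not depend on the classifier; this is an exact
optimization, not an approximation.

`paper_mode = TRUE` reproduces the classical full-data protocol —
pretreatment and selection fitted once on all samples, CV over the full
set — and logs a leakage warning; benchmark studies reporting
near-perfect CV accuracies typically follow that protocol, and both
behaviors must be available and labeled.

Any stage error is caught and recorded as a failed entry with its message;
a 90-cell study must degrade gracefully rather than abort. The winning
triple maximizes CV accuracy, with ties broken by test accuracy and then
lexicographically. Seeds for split, folds, selection and classifiers are
derived deterministically from one master seed (selection/classifier seeds
hash the triple name, so a cell's result does not depend on which other
cells were requested).

`correlate_trait` implements the companion analysis relating spectra to a
per-class chemical trait (e.g. crude protein or crude fat content, as
shipped in `inst/extdata/soybean_traits.csv`): each sample inherits its
class value and the per-band Pearson correlation is reported with its
maximizing wavelength.

## Numerical choices and degenerate inputs

* Ties everywhere resolve to the first (lowest) index: trace minima,
  coefficient orderings, component labels of equal size.
* `spectrum_set` validates shape, strictly increasing wavelengths and
  finiteness on construction, so downstream code never sees NaN.
* Degenerate inputs raise typed, named errors rather than propagating
  NaN: constant spectra (SNV), constant reference (MSC), zero panel DN
  (calibration), empty ROI masks (naming the threshold), classes smaller
  than the fold count (stratification).
* The RNG is always used through seeded, state-restoring wrappers; no
  exported function perturbs the caller's `.Random.seed`, and equal seeds
  give bit-identical results, including the ensemble and the network.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use deliberately modest problem
sizes — e.g. the full 90-cell smoke grid runs on 300 spectra x 128 bands,
selection oracles on 100 x 64, and the scatter-dominance property on a
2 x 2 x 2 subgrid over 20 seeds — chosen so the whole suite completes in a
few minutes on one CPU while still exercising every code path at the
default study design (1200 x 128) where that design itself is the thing
under test.

## Known limitations

* Real-data accuracies from any published study are not reproducible
  without that study's raw images; all quantitative checks here run on the
  synthetic generator's study conditions.
* The ENVI reader supports BIL/BIP/BSQ with data types 4 (float32) and
  12 (uint16), read-only; radiometric/dark-current calibration is assumed
  done upstream (an optional dark vector is accepted), and multi-seed
  scene splitting is out of scope.
* Pretreatments are applied singly; stacked pretreatments (e.g. SG then
  FD) are deliberately out of scope.
* The subspace-LDA ensemble and KDE naive Bayes are exact to their
  definitions but not speed-optimized for thousands of features.
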