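---
title: "Quantifying cadmium from LIBS spectra: models, selection algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cadmium from LIBS spectra: models, selection algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(libschemo)
```

## The analytical problem

Laser-induced breakdown spectroscopy (LIBS) records the atomic emission of a
laser-ablated micro-plasma. For plant material such as tobacco roots the
spectrum spans tens of thousands of wavelength channels, of which only a
handful carry information about the analyte — here cadmium, with Cd I
emission lines at 326.10, 340.36, 346.61, 361.05, 361.28, 361.44, 466.23,
467.81, 508.58 and 643.84 nm. Two noise mechanisms dominate quantification:

* **shot-to-shot fluctuation** — the pulse energy delivered to the plasma
  varies between shots, multiplying *all* line intensities of a spectrum by
  a common factor $f$;
* **matrix effects and detector noise** — matrix-element lines (Ca, Mg, Na,
  K, Fe, C, CN) respond to the bulk sample, and each channel carries
  additive noise.

`libschemo` implements the full calibration workflow for this setting:
wavelet preprocessing, a rank-ordered calibration/prediction split,
interval-based variable selection (iPLS, BiPLS), the successive projections
algorithm (SPA), univariate calibration with intensity-ratio indices, and
PLS / SVM multivariate calibration.

## The synthetic-data generator

No public LIBS dataset accompanies this problem, so the package ships a
simulator whose defaults encode the study design the analysis assumes:

* **Design.** Five Cd-stress groups of 12/12/18/18/18 samples; per-group Cd
  content is truncated-normal with means 0.001/0.015/2.304/6.663/11.577 and
  SDs 0.006/0.087/0.602/1.735/2.617 mg g⁻¹ (the reference ICP-OES
  statistics). The group-1 parameters are internally inconsistent with their
  printed min/max; they are taken verbatim and truncated at zero.
* **Axis.** 22,015 uniformly spaced channels over 229.99–880.01 nm
  (≈ 0.0295 nm spacing). The uniform grid keeps interval arithmetic exact,
  which is what the selection algorithms consume.
* **Lines.** A catalog of pseudo-Voigt profiles (default FWHM 0.1 nm,
  Lorentzian fraction `eta = 0.3`; no profile shape is prescribed by the
  application, so a configurable mix is provided). Analyte lines have height
  `sensitivity × cd`; matrix lines a fixed base height with an optional mild
  Cd trend (`matrix_trend = 0.02` per mg g⁻¹, echoing the observed increase
  of matrix-line intensity with Cd stress); Cd I 466.23 nm is configured
  *background-like* — fixed height, no Cd sensitivity — so it tracks the
  shot factor only. Profiles are rescaled so the channel nearest the line
  center carries exactly the nominal height, making peak heights exact on
  any grid. Each profile is evaluated within ±8 FWHM of its center.
* **Noise.** Per shot, one lognormal factor `f` (sdlog `shot_sigma`,
  mean-one parameterization) multiplies the entire line sum; additive
  Gaussian channel noise has SD `noise_sd`. A recorded spectrum averages
  `replicates` shots (default 80, the instrument's shot-averaging scheme)
  that share the sample's Cd content but not `f`. The default baseline is
  zero: denoised LIBS spectra are analysed peak-height-wise and a continuum
  term would only add a constant the calibrations absorb; a polynomial
  baseline is available via the `baseline` coefficients for robustness
  studies.
* **Sensitivities** (intensity units per mg g⁻¹) are package choices,
  ordered by the lines' practical usefulness: 508.58 nm is the strongest
  interference-free line (150); 361.05 nm strong (100) but adjacent to the
  Fe I 360.88 nm matrix line; the remaining Cd lines are weaker.

What the simulator deliberately does **not** model: plasma physics
(Saha–Boltzmann populations), self-absorption, detector gating, and
wavelength-dependent instrument response. Passing tests therefore
demonstrate the *chemometric* machinery — selection, ratio indices,
calibration — under the assumed noise structure, not instrument fidelity on
real tobacco-root spectra.

## Preprocessing

**Wavelet denoising.** Daubechies-6, decomposition level 3, soft
thresholding of the detail coefficients with the per-level universal
threshold `sigma * sqrt(2 log n)` where `sigma = MAD/0.6745` is estimated
from that level's coefficients — a standard, assumption-light rule (none is
prescribed by the application). The transform is implemented in the package
(no wavelet package is among the dependencies' tier for this stack): signals
are padded by symmetric reflection to a dyadic-divisible length, a
*periodized* orthogonal DWT is applied, and the pad is discarded after
reconstruction. This yields exact perfect reconstruction by construction
(round-trip error ~1e-15) while confining wrap-around artifacts to the
discarded pad — the practical benefit of symmetric extension without its
bookkeeping-heavy inverse.

**Split.** Samples are sorted by reference Cd content (stable sort); in each
block of four the first three go to calibration and the fourth to
prediction. A trailing partial block goes to calibration, so prediction is a
strict every-fourth subsample: 68 samples split 51/17. The split depends on
reference values only — never on spectra — so no spectral information leaks
across it.

## Variable selection

**Interval partition.** `partition_equidistant(p, k)` assigns the remainder
channels to the *leading* intervals (first `p mod k` intervals of size
`ceil(p/k)`). This remainder-first convention is the unique one consistent
with every entry of the 28-interval elimination ledger on 22,015 channels
(787-channel intervals 1–7, 786 thereafter) and with the 1,693-channel 8th
interval at `k = 13`. Intervals are 1-based closed index ranges — the native
R convention, and the numbering used in reports.

**Scoring.** Every interval model is a SIMPLS partial-least-squares
regression scored by leave-one-out RMSECV, minimized over 1..`max_lv`
latent variables. LOO is used for all PLS scoring (the LV-choice rule is
LOO; the fold scheme for interval scoring is otherwise unspecified, and LOO
avoids inventing a second scheme). Degenerate channel sets (no usable
covariance, e.g. all-constant) score as the LOO mean predictor with
`n_lv = 0`. Ties on RMSECV break toward smaller `k`, then lower interval
index (iPLS) / fewer channels (BiPLS, SPA) — runs are fully deterministic.

**iPLS** scans `k = 2..30`, scores every interval, and returns the single
best interval. **BiPLS** starts from all `k` intervals and repeatedly
removes the interval whose removal yields the lowest remaining-model
RMSECV; each ledger row records the state *before* that row's removal (the
channel count its model used), so the final row is the last surviving
interval. The best step of the best `k` defines the selected interval set.
`replay_elimination()` reproduces the channel bookkeeping of any removal
order by pure integer arithmetic — useful for auditing ledgers without
refitting models.

**SPA** greedily grows chains of minimally collinear channels: columns are
mean-centered and unit-norm scaled, and at each step every unselected
column is deflated against the span of the selection (modified
Gram–Schmidt); the largest residual norm wins, ties to the lowest index.
Chains from every candidate start are evaluated prefix-by-prefix with
leave-one-out RMSECV of an ordinary least-squares model (computed by the
PRESS identity, with explicit refits as fallback near-singular hats).
Classical SPA validates on a separate set; since no second split is
defined here, LOO on the calibration set is used instead — this keeps the
prediction set untouched.

## Calibration models

* **Univariate.** `concentration = a·x + b` by OLS on a line intensity
  (nearest-channel extraction by default, treating each channel as one
  variable; `window_max` mode tolerates registration offsets) or on a ratio
  index. RMSECV by LOO; R²/RMSEP on the prediction set.
* **Ratio indices.** `index1 = (I508.58 + I361.05) / (2·I466.23)`,
  `index2 = I508.58 / I466.23`. Because 466.23 nm tracks only the shared
  shot factor, the ratio cancels `f` exactly when additive noise is absent —
  the internal-standardization mechanism that motivates these indices. (The
  `index1` form divides by `2·I466.23`; the alternative reading that
  multiplies by the denominator line is not a ratio and would not cancel
  `f`.)
* **PLS.** SIMPLS, latent-variable count chosen by LOO RMSECV (ties toward
  fewer LVs). With all components on full-rank data it reproduces OLS — one
  of the test oracles.
* **SVM.** Epsilon-insensitive RBF support-vector regression on principal
  components of the calibration spectra (loadings fitted on calibration data
  only and frozen). Hyperparameters — cost {1, 10, 100, 1000}, kernel width
  2⁻⁸..2² (log grid), epsilon {0.01, 0.1}; none are prescribed, these are
  conventional ranges — are tuned by seeded fivefold CV RMSE; when `n_pcs`
  is `NULL` the component count (≤ 13) is chosen jointly. The reported
  RMSECV is the best tuning-fold RMSE, i.e. an *optimistic* estimate: no
  outer CV loop is nested around the tuning, since a single RMSECV per model
  is reported without a nesting prescription.

All selection, LV/hyperparameter choice and PCA loadings use the
calibration split only; the prediction split enters only the final metrics.
The test suite verifies this by corrupting prediction-set spectra and
asserting that no calibration-side artifact changes.

## Numerical choices and degenerate inputs

* SIMPLS stops extracting components when the deflated covariance or score
  norm falls below `1e-12` relative to its initial value; remaining
  component requests return the highest available prediction (with zero
  components, the calibration mean).
* LOO-capped bounds: PLS LVs ≤ `min(n − 2, p)`; SPA prefix length ≤
  `min(n − 2, m)`, so every scored model is LOO-estimable.
* Zero-variance columns are never picked by SPA (zero residual), and a
  zero-variance univariate predictor is an error.
* The truncated-normal concentration sampler rejects negative draws, so
  group means with mean ≫ SD are recovered essentially unbiased while the
  near-zero control group is clipped at 0.
* Profile heights are normalized at the channel nearest the line center, so
  doubling the concentration exactly doubles a noiseless analyte peak on any
  grid.

## Problem sizes used by the tests and the acceptance script

Exact integer properties (the 28-interval elimination ledger, the
`k = 13` interval sizes, the 68-sample split) run at the full
22,015-channel scale — they are arithmetic and take milliseconds. The
stochastic suites run on reduced designs chosen as the package's own
desk-scale benchmark: 25–40 samples, 651–1,301 channels over the same
229.99–880.01 nm range, 3 replicates. On 1,301 channels (0.5 nm spacing)
every catalogued line falls on its own channel, which the index tests need
(466.23 vs 467.81 nm). The selection-correctness benchmark additionally
uses pure-Gaussian profiles (`eta = 0`) and a catalog in which 508.58 nm is
the only concentration-sensitive line: with Lorentzian wings on a coarse
grid, genuine analyte signal leaks into the neighbouring interval's first
channel and "the interval containing the line" is no longer the unique
correct answer, whereas the Gaussian fixture makes the ground truth
identifiable. The acceptance script runs the end-to-end pipeline on the
78-sample five-group design over 1,301 channels.

## Known limitations

* The simulator's multiplicative noise is a single scalar per shot; real
  shot-to-shot variation has wavelength-dependent structure that ratio
  indices cancel only approximately.
* Reported SVM RMSECV is optimistic (see above); compare models on RMSEP.
* BiPLS recomputes a full LOO-PLS score for every candidate removal, which
  is O(k²) model fits per `k`; on the full 22,015-channel axis with many
  samples this is minutes-scale, and the `k_range` argument is the lever.
* The wavelet implementation is periodized-after-padding; coefficients are
  not bit-identical to symmetric-extension implementations in other tools,
  though denoising behaviour is equivalent in practice.
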