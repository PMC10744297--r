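---
title: "Methods: Raman spectral preprocessing and tissue classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman spectral preprocessing and tissue classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ramantissue)
```

## The problem

Raman spectroscopy probes the vibrational modes of tissue biochemistry:
protein, lipid and collagen bands shift in relative intensity between
healthy and malignant colorectal tissue. `ramantissue` implements a
complete, testable pipeline for binary tissue classification from Raman
spectra — preprocessing, dimensionality reduction, classical and deep
classifiers, patient-grouped validation, a preprocessing ablation harness
and Grad-CAM saliency — together with a patient-structured synthetic cohort
generator, because clinical spectra of this kind are typically private.
Every downstream stage is exercised end-to-end against simulated cohorts
with known ground truth.

## The spectral axis and regions

The default axis spans 500–3200 cm⁻¹ with 3165 points in two
piecewise-uniform segments (spacing 1100/1210 cm⁻¹ below 2800 cm⁻¹ and
300/476 cm⁻¹ above). These spacings are calibrated so that the standard
fingerprint region (700–1800 cm⁻¹), the CH-stretch region
(2800–3100 cm⁻¹) and their union select exactly 1211, 477 and 1688 grid
points — the dimensionalities of the acquisition axis this package
emulates. A real instrument's axis is rarely uniform in wavenumber at
constant detector pixel pitch, which is why a denser high-wavenumber
segment is physically plausible; the two-segment reconstruction is a
documented stand-in, not a claim about any particular instrument. Region
endpoints are compared with an absolute tolerance of 1e-6 cm⁻¹ so that
on-grid endpoints survive floating-point axis construction.

## The synthetic cohort generator

`generate_cohort()` emulates an ex-vivo study of 22 patients and 442
spectra (221 healthy / 221 cancerous; 10 per patient and class, with one
extra pair assigned to the first patient — a deterministic remainder
policy). Per spectrum, the model is

    y = clean(label, patient) * gain + A * b(nu) * s + noise + spikes,

clipped at zero, where

* `clean` is a sum of Lorentzian bands, L(ν) = (Γ/2)² / ((ν−c)² + (Γ/2)²).
  The default library places class-differential bands at 866, 1005, 1342,
  1437, 1671, 1748, 2852, 2890, 2935 and 2974 cm⁻¹ plus four weaker
  secondary bands (1250, 1330, 1450, 1658 cm⁻¹). Protein and collagen
  bands are up-modulated in the cancerous class (amplitude ratios 1.3 and
  1.2), lipid bands down-modulated (0.7), encoding the higher
  lipid-to-protein ratio of normal tissue. Fingerprint bands default to
  15 cm⁻¹ FWHM, CH-stretch bands to 40 cm⁻¹ — Lorentzian widths typical of
  condensed-phase Raman lines. True clinical effect sizes are unknown;
  these are simulator conventions, and no acceptance property depends on
  their exact values.
* `b(ν)` is a smooth autofluorescence shape (decaying exponential plus a
  broad Gaussian hump at 1400 cm⁻¹, unit maximum), scaled by
  `baseline_amplitude` (default 5, i.e. several times the band amplitudes)
  and a per-spectrum log-normal factor `s` (log-sd `baseline_sd = 0.3`) —
  tissue spots fluoresce unevenly, which is precisely why baseline
  correction earns its keep.
* `gain` is per-spectrum log-normal (log-sd 0.1), `noise` is i.i.d.
  Gaussian (sd 0.02), and `spikes` are sparse impulse artifacts
  (probability 5e-4 per channel, amplitude ~3) mimicking cosmic-ray hits.
* Patient-level random effects multiply the protein / lipid / collagen band
  groups (log-sd 0.15), drawn once per patient, so spectra cluster by
  patient — the reason leave-one-patient-out validation matters.

A single seeded RNG stream with fixed draw order (patient multipliers,
then per spectrum: gain, baseline factor, noise, spikes) makes cohorts
bitwise-reproducible. The generator does **not** model radiative transfer,
instrument response, Mie scattering or detector etaloning; passing tests
demonstrate pipeline correctness on structured synthetic data, not
clinical performance on real tissue.

## Preprocessing

* **SNIP baseline correction** (`snip_baseline`, default 80 iterations):
  iterative peak clipping `v_i <- min(v_i, (v_{i−m}+v_{i+m})/2)` with the
  half-window m growing from 1 to 80. Clipping is applied only where the
  full window fits inside the signal: clamping indices at the edges erodes
  any sloped background inward catastrophically (a 0–100 ramp acquires
  residuals of ~89 units). Clipping operates on intensities directly by
  default. The LLS compression ln(ln(√(y+1)+1)+1) is implemented
  (`lls = TRUE`) but off by default: it is designed for photon-counting
  spectra spanning many orders of magnitude, and on moderate-dynamic-range
  backgrounds its strong concavity makes the clipped baseline
  systematically undershoot (measured ~40 units low on the same ramp after
  80 passes). A decreasing window schedule is likewise available. With the
  defaults, a Lorentzian peak on a linear ramp is recovered to within 5%
  amplitude and the far field is flat to within one count.
* **L2 normalization** divides each spectrum by its Euclidean norm;
  **SNV** subtracts the mean and divides by the population (divide-by-n)
  standard deviation — the package fixes the denominator convention since
  usage varies.
* **Median filter** (window 5) and **Savitzky–Golay** (window 11, order 3)
  / **Gaussian** (σ = 2 samples, truncated at 4σ) smoothing all use
  reflect padding (mirror without repeating the edge sample), fixed and
  documented for reproducibility.

Pipelines (`pipeline_preset`) compose these stages; per-spectrum stages run
on the full grid, then the wavenumber region is cut, then PCA (if any) is
fitted — on training folds only inside cross-validation, with the fitted
state reused on held-out data. Presets: `paper_ml` (SNIP, L2, median,
region, PCA(30)), `paper_dl` (SNIP, L2, region), and three reference
pipelines `pipeline_a/b/c` (Savitzky–Golay|Gaussian + SNIP + SNV + PCA, and
SNIP + SNV + Savitzky–Golay without PCA — the stage lists followed
literally). Negative intensities after baseline subtraction are kept, not
clipped.

## Dimensionality reduction

PCA is computed by full SVD of the mean-centered matrix — deterministic,
seed-free. `variance_table()` reports cumulative explained variance at 10,
20, 30 and 40 components. Whole-cohort variance reports are offered
alongside the leakage-safe per-fold fit used in cross-validation; the
package defaults to per-fold refitting inside CV because a globally fitted
projection would let validation spectra influence the training
representation.

## Classifiers

Classical families wrap established implementations with fixed, seeded
defaults: ridge logistic regression (glmnet, λ = 1e-4), RBF SVM (e1071,
C = 1; probabilities via deterministic Platt scaling fitted with `glm` on
training decision values, because libsvm's built-in calibration draws from
an unseeded C RNG), random forest (100 trees) and XGBoost (200 rounds,
learning rate 0.1, depth 3, L2 regularization 1e-4).

The deep families are built on the package's own array-based layer engine
(no external deep-learning framework is used):

* `cnn1d`: conv(10 filters, kernel 3) → ReLU → batch norm → dropout →
  conv(25 filters, kernel 3) → ReLU → batch norm → dropout → average
  pool(8) → flatten → dense(1) → sigmoid.
* `resnet1d`: three residual blocks (16/32/64 channels; two
  conv(3)+batch-norm layers each, identity shortcut with a 1×1 projection
  on channel change), global average pooling, dense(1) → sigmoid.

Training uses Adam (lr 0.001), binary cross-entropy, 40 epochs, batch 32,
and an L2 weight penalty of 1e-4 on conv/dense kernels. Design points the
architecture description leaves open, fixed here: dropout rate 0.25 after
each batch-norm (configurable); "same" zero padding so feature maps stay
aligned with the input axis (needed for saliency); Glorot-uniform
initialization; batch-norm ε = 1e-3 with running-statistics momentum 0.9
(the value that makes short training runs usable for inference); inputs
are the preprocessed intensity vectors with a singleton channel axis.
Weight initialization, shuffling and dropout all draw from the seeded R
RNG, so training is exactly reproducible. Analytic gradients are verified
against central finite differences layer-by-layer in the test suite.

## Validation and metrics

`lopo_splits()` holds out each patient in turn; `grouped_kfold_splits()`
deals whole patients into k spectrum-count-balanced groups (seeded). The
deep models use patient-grouped folds too: spectrum-level folds would leak
patient-specific signal into validation. Pooled (micro) confusion matrices
are the primary report — per-fold accuracies are retained — with per-class
precision/recall/F1, accuracy, and support-weighted averages; reported
tables round to 1 decimal while raw values are kept. The ablation harness
evaluates the cumulative sequence raw → +SNIP → +L2 → +median → +PCA(30)
on identical folds and reports per-step deltas whose sum telescopes to the
total improvement exactly. The harness region-selects at every step for
comparability. Ablation "recall" is the support-weighted recall, which
equals accuracy at exact class balance; per-class recalls are stored as
well.

## Grad-CAM saliency

For a trained convolutional model, the class-score gradient is taken at
the pre-sigmoid logit (avoiding saturated-sigmoid vanishing gradients) with
respect to the last convolutional layer's feature maps — for the residual
network, the last block's output. Per-filter weights are the spatial mean
of the gradient; the rectified weighted sum of feature maps is linearly
interpolated to the input length, then min–max normalized (an identically
zero map is returned un-normalized with a degenerate flag).
`aggregate_saliency()` averages maps over spectra — mirroring a
whole-cohort heat map — and extracts contiguous bands above a threshold
(default 0.5 of the maximum).

Two practical caveats, both visible in simulation and worth knowing when
interpreting maps: per-spectrum normalization redistributes a localized
class difference into every channel (tall shared bands become
anti-discriminative through the norm), and concatenating disjoint
wavenumber regions creates a step discontinuity at the seam that
convolutional saliency can latch onto. The localization experiment in the
acceptance suite therefore trains on baseline-corrected, un-normalized
spectra over the uncut grid.

## Problem sizes and numerical choices

The test and acceptance experiments run at deliberately modest sizes
chosen as representative desk-scale studies: the default 22-patient,
442-spectrum cohort on the 3165-point axis for the label-recovery and
leakage checks; 12-patient cohorts on a 4 cm⁻¹-spaced axis (676 points)
for the saliency and ablation-direction experiments; 40 training epochs
for the compact CNN. Zero-norm and zero-variance spectra raise explicit
errors rather than propagating NaN; empty region selections name the
offending interval; simulator configuration errors list every offending
field. Ties in the median filter are resolved by the sort-based median of
an odd window (always a data value).

## Known limitations

Simulated evidence cannot certify clinical accuracy; the reported
synthetic accuracies characterize the pipeline, not tissue. The
1D-ResNet's depth/filter plan (3 blocks, 16/32/64) is a fixed design
choice where the emulated architecture is described only loosely. The
pipeline-C preset feeds raw-dimensional spectra to the classifier, since
its printed stage list ends without PCA. Transfer learning, data
augmentation, hyperparameter search and statistical model comparison are
deliberately out of scope.
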