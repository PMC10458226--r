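---
title: "Hybrid Raman/LIBS chemometrics: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid Raman/LIBS chemometrics: models, defaults, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramlibs)
```

## The problem

Portable instruments that combine laser-induced breakdown spectroscopy
(LIBS, atomic/molecular plasma emission on a wavelength axis) with Raman
spectroscopy (molecular scattering on a Raman-shift axis) promise better
authentication of look-alike products — e.g. distinguishing sixteen
Alpine-style cheeses or seven Arabica coffee brands — than either modality
alone, because elemental and molecular signatures are complementary.
`ramlibs` implements the full chemometric chain for such paired
acquisitions: axis handling, preprocessing, interfering-line removal, two
data-fusion strategies, feature selection, and repeated cross-validated
classification. Because curated food spectra of this kind are not publicly
distributable, the package ships a synthetic-data generator that emulates
the statistical structure of the two modalities; all pipeline claims are
validated against it and against closed-form oracles.

## Spectral axes

Both modalities share one compact spectrometer: LIBS on a uniform
2000-channel wavelength grid over 350–625 nm (0.33 nm resolution class),
Raman on a uniform 600-channel shift grid over 750–2800 cm⁻¹ relative to a
532 nm continuous-wave excitation. The Stokes-side conversion is
`shift = 1e7 (1/λ₀ − 1/λ)` with wavelengths in nm; it is exact, strictly
monotone, and inverted in closed form. Vacuum wavelengths are used
throughout — an air-index correction would move lines by well under the
channel width. With these grids the Raman span maps to about 554.1–625.1
nm, so the two modalities overlap above ~554 nm; in simultaneous
acquisition the sodium plasma line at 588.9 nm lands near 1816 cm⁻¹
(≈1820) inside the Raman window and must be subtracted.

## Synthetic-data generator

Each dataset family fixes a set of peak positions shared by every class:

* LIBS lines (Lorentzian, default FWHM 0.7 nm ≈ two channels): CN 388.2,
  Ca II 393.4, Ca I 422.7, C₂ 516.2, Na 588.9 nm. The calcium wavelengths
  are the canonical strong Ca II/Ca I lines inside the instrument range;
  elemental Ca/Na amplitudes dominate the molecular bands, as observed in
  food plasma spectra.
* Raman bands (Gaussian, default FWHM 12 cm⁻¹): 890, 1287, 1432, 1670
  cm⁻¹ for the cheese-like family; 1440, 1570, 1650 cm⁻¹ for the
  coffee-like family.

Classes differ **only** in per-peak amplitude multipliers, drawn once
(log-normal around 1) from a dedicated frozen seed, so class identities
are fixed study conditions independent of the noise seed. On top of the
class template the generator adds a fluorescence baseline for Raman
(order-3 polynomial, ~30% of the largest band) and a constant offset for
LIBS, one log-normal multiplicative factor per spectrum (σ = 0.10,
shot-to-shot plasma/laser fluctuation), and additive white noise per
channel.

**Complementarity.** Each class is assigned a *strong* modality in which
its multipliers carry the full between-class spread, and a *weak* one with
a reduced spread — half the classes are LIBS-strong, half Raman-strong.
This replaces an all-or-nothing variant (half the classes varying *only*
in LIBS, the rest *only* in Raman), which caps single-modality accuracy
near 55% for 16 classes: with identical templates in the other modality a
classifier can do no better than chance within half the label set, and no
noise level can land it in the realistic 80–85% regime where the published
single-modality systems operate. Graded strong/weak information keeps both
modalities individually useful while still making fusion demonstrably
beneficial.

**Calibrated defaults.** After normalization a spectrum's information sits
in its relative peak pattern, so a P-peak modality has only P−1 effective
dimensions: 4 for LIBS, 2–3 for Raman. The Raman multiplier spreads are
therefore wider than the LIBS ones (between-class log-SD 0.30/0.45 vs
0.15/0.12 per family; weak-modality 0.20/0.25 vs 0.07), and the additive
noise defaults
are per family (0.006 of the maximum peak signal for the 16-class family,
0.015 for the 7-class one). These values were calibrated once — at the
validation problem sizes below — so that either modality alone classifies
at roughly 0.78–0.88 macro accuracy under the standard pipeline, and then
frozen. They are calibrated, not fitted: no public per-class variance
estimates exist for the real foods.

**What the generator does not emulate:** band-position shifts between
classes, matrix effects and self-absorption in the plasma, detector
nonlinearity, cosmic-ray spikes, wavelength-calibration drift, or
correlated (pink) noise. Passing tests therefore demonstrate that the
pipeline machinery is correct and that fusion helps under the stated
statistical model — not that these accuracies transfer to any particular
real instrument or food.

## Preprocessing

The conditioning chain is baseline → denoise → normalize → transform,
applied per spectrum:

1. **Baseline.** Raman: asymmetric least squares (Whittaker smoother with
   a second-difference penalty; smoothness 1e5, asymmetry 0.01, 10
   reweighting iterations), solved by a banded LDLᵀ factorization. LIBS:
   subtraction of the per-spectrum minimum (the broad fluorescence problem
   is specific to Raman).
2. **Denoise.** Savitzky–Golay, window 11, order 3, both modalities —
   polynomial signals up to cubic pass untouched.
3. **Normalize.** Total intensity to one, removing the global
   multiplicative fluctuation exactly. Negative baseline residuals are
   clipped at zero first, so totals stay positive.
4. **Transform.** Channel-wise square root, a variance-stabilizing choice
   that damps residual multiplicative effects; `identity` and `log1p` are
   selectable alternatives since the transformation is a modelling choice
   rather than a fixed convention.

Interfering-line subtraction (simultaneous mode only) happens **before**
this chain, in raw intensity space, where the Lorentzian line model is
additive: the Na line is fitted (center, FWHM, amplitude + constant local
background, Levenberg–Marquardt, ±2 nm window) and the evaluated
Lorentzian — without the background term — subtracted inside the window,
clipped at zero.

## Fusion, selection, classification

Two fusion strategies are implemented. *Early fusion* concatenates the
full preprocessed spectra into one 2600-channel hybrid vector (LIBS block
first) before any selection; per-modality normalization has already
equalized the blocks' scales. *Late fusion* filters and selects each
modality independently and concatenates only the selected features, so the
fused width is exactly the sum of the per-modality feature counts. An
optional overlap coaddition (summing the two signals on a common
wavelength grid inside the ~554–625 nm overlap) is available as a
sensitivity variant, off by default, since co-assembly into one matrix is
what reproduces the documented fused dimensionalities.

Selection is two-stage. A one-way ANOVA F filter keeps the 200
highest-F channels (ties to the lower index). The multivariate stage is a
multinomial logistic regression with the elastic-net penalty

$$-\frac1n \sum_{i=1}^n \sum_{k=1}^K 1(y_i{=}k)
\log\frac{e^{x_i^\top\beta_k}}{\sum_l e^{x_i^\top\beta_l}}
+ \lambda \sum_k\Big[\alpha\|\beta_k\|_1
+ \tfrac12(1-\alpha)\|\beta_k\|_2^2\Big],$$

which selects features (nonzero coefficients) while it builds the
classifier. The solver is written for this package: block coordinate
descent over classes with a weighted least-squares surrogate per class
(Newton weights `p(1−p)` floored at 1e-5; a fixed-¼-curvature
majorize–minimize mode guarantees a monotone objective and serves as the
debug/diagnostic mode), soft-thresholding updates, warm starts along a
descending λ path, sequential strong-rule screening verified against the
KKT conditions, and active-set cycling. Features are standardized
internally (zero mean, unit 1/n-variance); coefficients are reported on
the standardized scale; intercepts are unpenalized. Convergence is
declared when the largest coefficient change in a cycle drops below the
threshold (default 1e-6; the cross-validation pipeline passes a looser
1e-3 through its configuration, which does not change winners in
practice). The symmetric K-vector parameterization is over-parameterized
at λ = 0; the penalty resolves it for λ > 0, and no sum-to-zero constraint
is imposed.

Tuning searches α over a grid and λ over a log-spaced path from the
closed-form `λ_max` (the smallest penalty with an all-zero solution)
down to `1e-4·λ_max` by default, by repeated stratified CV deviance,
taking the minimum-deviance pair (no one-standard-error rule — the
simpler default) with ties to the sparser model.

Evaluation runs independent *sessions* (default ten, seeds 1…10) of
stratified 10-fold CV. Every data-dependent step — ANOVA filter,
elastic-net tuning and selection, classifier training — is refit inside
each training fold, so no selection information leaks into held-out folds.
Fold predictions pool into one confusion matrix per session; the headline
number is the mean over sessions of the macro accuracy (mean per-class
recall, i.e. the normalized confusion diagonal), with the SD taken across
sessions; micro (overall) accuracy is reported alongside. A linear SVM
(one-vs-one, cost tuned over {0.1, 1, 10} by inner 5-fold CV) trained on
the elastic-net-selected features is the benchmark classifier; the kernel
is this package's choice.

## Validation scale and numerical choices

The validation suite exercises the fusion-benefit and null-calibration
properties at reduced problem sizes chosen as this package's standard
validation conditions: 20 replicates per class for the 16-class family and
30 for the 7-class family, tuning grid α ∈ {0.1, 0.5, 1} with 20 λ values
down to `1e-2·λ_max`, holdout tuning inside each training fold, and solver
threshold 1e-3. Full-scale nested cross-validation at 100 replicates per
class (1600 × 2600 hybrid matrices, ten sessions of ten folds, each fold
retuning the full grid) is a multi-hour computation for any coordinate
descent implementation and adds nothing to the properties being checked.
The generator's noise calibration was performed at these validation sizes.

Other numerical decisions: peak centers are refined by 3-point parabolic
interpolation (otherwise the 0.33 nm channel pitch quantizes line
positions); the local background inside a line-fit window is a constant
(windows are ±2 nm); fit initialization takes the most central detected
peak, amplitude from the window range, FWHM from the half-maximum
crossings; degenerate inputs (flat windows, all-zero spectra, constant
channels, empty masks) are either exact fixed points or explicit errors,
as documented per function; an elastic-net fit whose active set is empty
degrades to the intercept-only prior model inside the CV loop rather than
aborting a session.

## Known limitations

* The generator's class model is amplitude-only; real food spectra also
  shift and reshape bands, so absolute accuracies here do not transfer.
* Cross-validated accuracies from refit-inside-folds protocols are not
  directly comparable to published numbers computed under unknown (and
  possibly more optimistic) selection protocols.
* The ALS baseline assumes a smooth background; sharp fluorescence edges
  would leak into the signal estimate.
* Anti-Stokes axes, Voigt line profiles, multi-line joint deconvolution,
  and decision-level fusion are out of scope.
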