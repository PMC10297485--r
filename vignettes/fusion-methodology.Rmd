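---
title: "Mid-level fusion of TLC imaging and Raman data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mid-level fusion of TLC imaging and Raman data: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saffusion)
```

## The screening problem

Saffron powder is screened for four adulterants — safflower and turmeric
(plant bulking agents, spiked at 20–100% w/w) and the synthetic dyes red 40
and yellow 5 (spiked at 2–10% w/w, since a little dye matches the color of a
lot of plant material) — plus the pure class. Two cheap measurements are
taken from one TLC chip: a photograph of the dried sample pattern under
ambient and 365 nm UV light, and Raman spectra (100–2200 cm⁻¹) collected at
five spots per replicate. Neither block suffices alone; `saffusion`
concatenates features from both (mid-level fusion) before modelling.

## Feature extraction

**Imaging.** The ambient and UV photographs are merged side-by-side into one
composite, split into RGB channels, and the red channel discarded (it
carries almost no pattern contrast on these chips). Twenty sampling points
are placed per pattern — ten on the circle at half the pattern radius, ten
at mid-ring — equally spaced in angle; half of each set reads the ambient
half of the composite and half the UV half, so both lights contribute to
every region. At each point the maximum, minimum and mean of a 32 × 32 px
window are taken for the green and blue channels: 20 points × 2 channels ×
3 statistics = 120 variables, 7560 values over the default 63-pattern
design. "Lightness" is the raw 8-bit channel value; no colorspace transform
is applied, because the channel-split workflow operates directly on RGB
planes. The pairing of lights with channels is a genuinely open convention;
the composite scheme above is the package's fixed default, and the point
counts and window size are arguments of `extract_imaging_features()`.
Coordinates are 0-based (x = column, y = row) and even-sized windows are
biased toward the top-left, fixed so results are bit-reproducible.

**Raman.** Featured Raman variables are the raw intensities inside the four
crocin band windows 1000–1050, 1130–1240, 1270–1300 and 1500–1580 cm⁻¹,
inclusive at both ends (274 variables on the default 1 cm⁻¹ grid). No
baseline correction or smoothing precedes windowing. Windows are used
as-is by default; VIP selection (`compute_vip()`, standard definition
`VIP_j = sqrt(p · Σ_a SSY_a (w_ja/‖w_a‖)² / Σ_a SSY_a)`, threshold 1) is
offered separately to audit or re-derive the windows rather than silently
replacing them — on synthetic data the mean VIP inside the crocin windows
exceeds the mean outside, which is the property the windows encode.

## Normalization, fusion and models

Both blocks are min-max normalized per variable, x* = (x − min)/(max − min).
The parameters are fitted **on the training partition only** and applied to
validation rows without clipping (a validation value may map outside
[0, 1]); fitting them on all rows would leak the held-out range into RMSEP.
Constant (zero-range) variables map to 0 rather than erroring, because
saturated yellow-5 channels legitimately produce constant columns. The
fused matrix is the column-wise concatenation, Raman variables first, with
the boundary recorded so fusion is exactly invertible.

The PLS engine is NIPALS with X-only deflation and a Y-scores inner loop
(convergence tolerance 1e-10 on the score vector, at most 500 iterations
per component; the inner loop is exact in one pass for single-response
models). Components stop early when the X residual norm falls below 1e-8 of
its initial value (rank exhaustion), and the achieved count is recorded.
With all components on full-rank data the coefficients equal the
least-squares solution, which the tests use as one oracle; an independent
PLS implementation is the other.

* **Classification** is PLS-DA: the class labels become a one-hot indicator
  matrix (columns in alphabetical class order, which also fixes the
  tie-break: exact ties in the argmax go to the alphabetically first
  class), and predictors are Pareto-scaled inside the fit — the scaling
  convention of these classification models, damping noise variables
  without flattening strong bands. Zero-variance columns are left centered
  at zero.
* **Quantification** consumes blocks that are already min-max normalized,
  so the regression is only mean-centered. One model is fitted per
  (adulterant, block) pair on that adulterant's training samples plus pure
  saffron as the level-0 calibration point; natural and artificial
  adulterants are never pooled, since their level ranges differ by an
  order of magnitude and a pooled RMSE would be dominated by the natural
  scale.

Component counts are chosen by grouped K-fold cross-validation (default 7
folds): rows sharing a group id — (class, level, replicate) for
classification, (level, replicate) for quantification — never straddle a
fold, so the five Raman spots of one replicate cannot leak across the
split. RMSECV(a) is computed from the pooled out-of-fold residuals and the
chosen count is the argmin, ties toward fewer components. This argmin rule
is an explicit stand-in for proprietary "significance" rules in commercial
chemometrics software, which are not published.

Evaluation reports per-class correct rates plus **both** overall
conventions — micro (total correct / total members) and macro (mean of
per-class rates) — because published misclassification tables mix the two;
`adulterated_vs_pure_rate()` reports the screening-critical percentage of
adulterated samples not classified as pure. R² is the calibration
(goodness-of-fit) coefficient on the training stream; RMSECV and RMSEP come
from the cross-validated and external prediction streams respectively.

## What the synthetic generator emulates — and what it does not

The generator reproduces the measurement *design*: 4 classes × 5 levels ×
3 replicates × 5 spots + pure = 315 spectra, collapsed over spots to 63
patterns; the stratified split draws whole (replicate, spot) groups per
class, giving 50 training / 25 validation spectra per adulterant and 10/5
for pure (210/105 overall). Spectra follow exact linear mixing:
`(1 − level/100)·saffron + (level/100)·adulterant + baseline + noise`, with
Gaussian-peak templates whose saffron (crocin) centers (~1020, 1165, 1210,
1285, 1536 cm⁻¹) lie inside the featured windows. Chip colors interpolate
between the pure color and the class color with a per-class gain: plant
adulterants have gain 1, dyes gain ≈10–17 reflecting their far stronger
tinting, and yellow 5's gain of 100/6 makes the chip color saturate exactly
at the 6% threshold, above which the saturation rule also pegs the ambient
green channel at 255 — so imaging carries no level information for yellow 5
above 6% w/w, by construction. Noise is additive i.i.d. Gaussian per grid
point / per pixel (Raman sd 15 counts, image sd 6 of 255 by default) — the
simplest model adequate for within-sampling-error testing; replicate-level
variance magnitudes are free parameters, not estimates from real
measurements. Every slot's seed derives deterministically from the master
seed and its label, so any subset regenerates bit-identically.

The `"ambiguity"` preset encodes the complementary blind spots: turmeric
and red 40 render in nearly identical chip colors (imaging-only models
confuse them), while the two dyes' Raman signatures are weak and nearly
identical, so at 2–10% w/w Raman-only models confuse red 40, yellow 5 and
pure. Passing the fusion-superiority tests under this preset shows the
pipeline *can* exploit complementary blocks; it does not certify
performance on real chips, where band shapes are non-Gaussian, baselines
fluoresce, droplets diffuse anisotropically, and replicate variance is
structured rather than i.i.d. Physically realistic band shapes, TLC
transport modelling and instrument response are deliberately out of scope.

One structural consequence worth stating: because saturation deliberately
destroys level information, the "noiseless ⇒ zero prediction error" limit
holds for every (adulterant, block) cell only with saturation disabled; with
saturation on it holds for the Raman and fused cells, and that asymmetry is
exactly the mechanism by which fusion improves yellow-5 quantification.

## Problem sizes and runtime choices

All shipped tests and the acceptance script run the full default design
(315 spectra of 2101 points, 63 pattern pairs of 128 × 128 px, chosen so a
32 × 32 window fits inside every sampling point) — a full three-block
experiment takes a few seconds — and the fusion-superiority properties are
aggregated over five master seeds (pass rule ≥ 4/5, leaving room for an
occasional tie at near-ceiling accuracy). Small PLS oracle comparisons use
n = 8–15, p = 3–6 over 20 random draws.

## Known limitations

* The generator's color model is affine in (gained) level; real chip color
  response is nonlinear well before full saturation.
* PLS-DA assignment is a bare argmax — no probabilistic calibration, no
  "none of the above" rejection — matching hard misclassification tables
  but unsuitable for open-set screening.
* Min-max normalization is sensitive to single extreme training values;
  robust range estimates are not implemented.
* VIP is computed from a single fitted model; no stability selection
  across cross-validation folds.
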