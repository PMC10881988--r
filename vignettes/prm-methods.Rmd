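---
title: "Penalized reference matching for hyperspectral Raman stacks: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized reference matching for hyperspectral Raman stacks: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prmsrs)
```

## The problem

A hyperspectral stimulated Raman scattering (SRS) stack holds one full
CH-stretching-region spectrum (roughly 2700–3150 cm⁻¹) per pixel, typically
75 bands about 6 cm⁻¹ apart. Lipid subtypes — cholesterol, triacylglycerols,
phospholipids, sphingolipids — differ in this window only through subtle
shape changes: the relative weight of the CH₂ band near 2850 cm⁻¹, the CH₃
band near 2935 cm⁻¹, the 2880 cm⁻¹ Fermi-resonance region, and the olefinic
=C–H band near 3065 cm⁻¹. Plain cosine matching (spectral angle mapping)
against a pure-standard library fails in practice because pixel spectra are
displaced along the wavenumber axis by a few cm⁻¹ — chemical environment,
calibration drift, thermal effects — and a rigid inner product punishes a
shape match that is merely offset.

## The score

Both the pixel spectrum and the reference go through the identical chain:

1. optional baseline removal (measured background subtraction, or an arPLS
   estimate when no background is available);
2. linear interpolation onto a common 1 cm⁻¹ grid over the CH window, so
   inner products are dimensionally meaningful;
3. min–max normalization \((I - I_{\min})/(I_{\max} - I_{\min})\), which
   removes overall intensity and offset — the score responds to spectral
   *shape* only;
4. division by the Euclidean norm, making the inner product a cosine
   similarity.

With \(u\) the preprocessed pixel spectrum and \(v\) the reference, the
similarity score is

\[
\mathrm{score} = \max_{\Delta x} \left( u \cdot v_{\Delta x} - \alpha\,\Delta x^2 \right),
\]

where \(v_{\Delta x}\) is the reference slid by \(\Delta x\) grid steps
(zero-padded on the leading side, trimmed on the lagging side) and
\(\alpha\) (units cm², so \(\alpha\,\Delta x^2\) is dimensionless) prices
each unit of displacement. Because min–max normalization makes both vectors
nonnegative and unit-norm, the unshifted term is a nonnegative cosine and
Cauchy–Schwarz caps every term at 1: the score always lies in \([0, 1]\),
with 1 attained exactly by a perfect shape match at zero offset. This
boundedness is the practical advantage over least-squares unmixing
coefficients, which are unbounded and can be negative (see below).

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 1e-4 | cm² | penalty per squared cm⁻¹ of offset; 30 cm⁻¹ costs 0.09 |
| `max_shift` | 30 | cm⁻¹ | half-width of the offset search |
| `shift_step` | 1 | cm⁻¹ | offset grid; equals the interpolation step |
| `grid_range` | 2700–3150 | cm⁻¹ | CH-stretching fit window (451 points) |
| `grid_step` | 1 | cm⁻¹ | interpolation spacing |
| `arpls_lambda` | 1e5 | — | Whittaker smoothness of the arPLS baseline |

`alpha = 1e-4` is the regime in which the penalty meaningfully
discriminates: lowering it toward 0 lets any reference slide until it finds
its best alignment anywhere in the window, saturating scores
(under-penalization); raising it several-fold effectively forbids offsets
and reverts to rigid matching, taxing genuinely jittered pixels
(over-penalization). The `±30` cm⁻¹ search range covers realistic
calibration drift while the default penalty already dominates at its edge
(`alpha * 30² = 0.09`).

The offset search runs on the integer interpolation grid. Sub-grid
(continuous) offset optimization is deliberately out of scope: observed
displacements of several cm⁻¹ are large against a 1 cm⁻¹ grid, and a
discrete argmax keeps the scorer exact, cheap, and trivially deterministic.

### Which side shifts, ties, and degenerate pixels

Sliding the pixel or sliding the reference are equivalent up to the sign of
\(\Delta x\); this implementation slides the **reference** (positive =
toward higher wavenumber) so that per-pixel preprocessing is computed once
and reused across the whole library. At exactly equal maxima the smallest
\(|\Delta x|\) wins, then the negative offset — a fixed, documented rule so
reruns are reproducible to the bit. Constant or zero pixel spectra cannot
be normalized; they are masked with score 0 (never `NaN`, so downstream
ratio images stay computable), and the mask is carried on the score image.

A determinism contract holds throughout: stack scoring gives bit-identical
output for any chunked decomposition of the pixel set. The per-shift dot
products are accumulated in fixed column order per pixel (rather than
through shape-dependent BLAS kernels) precisely so this contract survives
any chunk size.

### The closed form used in testing

If the pixel is an exact copy of the reference displaced by \(k\) grid
steps and no support is clipped at the window edges, the score curve peaks
at \(\Delta x = k\) with value \(1 - \alpha k^2\). This holds only when the
reference's shifted autocorrelation falls off faster than the quadratic
penalty relaxes; broad bands (widths of 15–20 cm⁻¹, typical of real lipid
spectra) violate it near the optimum, where a slightly smaller offset can
buy more penalty relief than it loses in alignment. The test fixtures for
the closed form therefore use narrow synthetic bands (σ = 3 cm⁻¹); the
identity `score = 1 - alpha k²` is then exact to 1e-9 over the whole ±30
range.

## The pseudo-inverse baseline

For comparison, `pinv_unmix()` solves the per-pixel least-squares problem
\(\min_c \lVert R\,c - s\rVert_2\) with the unit-norm library spectra as
the columns of \(R\) (QR solve; Moore–Penrose minimum-norm fallback when
\(R\) is rank-deficient). Per-pixel solving — rather than a joint
image-wide solve — makes each pixel's coefficients independent of the image
it is embedded in, which is the property that makes maps comparable across
acquisitions. Coefficients are computed on the same preprocessed spectra as
PRM scoring so the two methods see identical inputs; on noiseless spanned
mixtures PINV recovers the true weights to machine precision, but on
correlated libraries its coefficients go negative and are unbounded, the
qualitative contrast with the \([0,1]\)-bounded PRM score that the test
suite asserts directly.

## Downstream image products

* **Ratiometric maps** divide two score images pixelwise; denominators
  below `epsilon = 1e-6` are masked rather than amplified, and input masks
  propagate as a union, keeping summary statistics honest.
* **Top-percentile spectra** summarize the pixels at or above the
  `pct`-th linear-interpolation percentile of unmasked scores by the mean
  and per-band standard deviation of their preprocessed spectra — the
  standard check that high-scoring pixels really resemble the reference.
* **Threshold masks** are monotone in the threshold by construction.
* **Channel merges** are additive composites with fixed \([0,1]\)
  per-channel scaling (no per-image stretch), so composites from different
  stacks remain comparable; clipped values are counted.
* **Agreement metrics** against a second modality report a structural
  similarity index (7×7 uniform windows, sample covariances, constants
  0.01² and 0.03² on the unit range — the standard formulation, validated
  against an independent implementation on a frozen fixture) and the
  normalized mean squared error \(\lVert a-b\rVert^2 / \lVert b\rVert^2\),
  both after joint min–max scaling to \([0,1]\). The exact windowing
  convention of a similarity index is not standardized across tools; the
  defaults here are stated so results are reproducible.

## Reference characterization

`fit_four_gaussians()` decomposes a CH-window reference into four Gaussian
components by bounded nonlinear least squares (Levenberg–Marquardt),
initialized on the canonical band assignments 2850 / 2880 / 2935 / 3065
cm⁻¹ with amplitudes bounded below by zero and widths confined to
[2, 100] cm⁻¹. The initialization and bounds are this package's own choices
— they are what make the fit reproducible — and users can override the
starting centers. On synthetic four-Gaussian truths the fit recovers all
twelve parameters to well under 1% relative error without noise and under
5% at 1% additive noise.

## What the synthetic generator does and does not emulate

`make_stack()` builds stacks the way the pipeline will meet them: mixtures
with known per-pixel weights on a fine 1 cm⁻¹ grid, a random per-pixel
brightness factor (uniform 0.5–2) so intensity invariance is exercised, a
per-pixel spectral jitter (Gaussian, default σ = 3 cm⁻¹) applied by
re-interpolation, additive Gaussian noise (default σ = 0.01 of a unit
peak, clamped at zero as a detector would), and finally resampling to 75
bands at 6 cm⁻¹ spacing so the pipeline's own re-interpolation path is
exercised end-to-end. Everything is a pure function of the settings and the
seed. Default image sizes (16×16) keep the full test suite and acceptance
run in seconds; the scoring path itself is size-independent.

Two reference families ship with the generator. `demo_peak_sets()` gives
three broad-band lipid-like spectra (CH₂-dominant, CH₃-dominant,
2880-dominant) for discriminability and mixture tests.
`penalty_demo_peak_sets()` is a deliberately *shift-confusable* pair for
studying the penalty regime: the wrong reference's dominant band is
unreachable within the search range, but a weak satellite sits 20 cm⁻¹
from the matched reference's main band. Under per-pixel jitter this
reproduces the qualitative penalty trade-off: matched-vs-unmatched contrast
peaks at the default coefficient and degrades both at a quarter and at four
times its value — at low α the satellite slides into alignment and inflates
false scores, at high α genuine jitter is taxed.

What the generator does **not** emulate: shot noise and lock-in transfer
functions of a real SRS detector, spatial point-spread correlation between
pixels, fluorescence bleed-through, and measured (rather than Gaussian-sum)
reference line shapes. Passing tests on these fixtures therefore
demonstrate the correctness and the qualitative behavior of the algorithms,
not instrument-level performance on tissue.

## Numerical choices and edge cases

* Grid points outside a spectrum's measured range are zero-filled and
  flagged rather than erroring; the flags ride along on the score image.
* Min–max before windowing vs after: normalization happens **after**
  restriction to the grid window, so references spanning the fingerprint
  region normalize consistently with CH-only pixels.
* The arPLS iteration stops when the weight vector's relative change drops
  below 1e-6, when the baseline touches the signal from below, or at 50
  iterations (with a warning); on noiseless smooth signals the negative
  residuals shrink to numerical noise and the logistic weights would
  chatter forever, so that state is detected and treated as converged.
* TIFF score maps in 8-bit mode use the fixed mapping `round(score · 255)`
  (half-even), never a per-image stretch, so exported images are comparable
  across references and stacks. Stack intensities are stored [0,1]-scaled
  with the scale factor in the JSON sidecar, round-tripping well within
  float32 precision.
* Scores are clamped to \([0,1]\) after the maximization purely to absorb
  last-bit floating-point excursions; the mathematics already bounds them.

## Known limitations

* The shift search is discrete; a true sub-cm⁻¹ displacement lands on the
  nearest grid offset.
* arPLS behavior on strongly curved fluorescent backgrounds depends on
  `arpls_lambda`; the 1e5 default suits the smooth backgrounds typical of
  the CH window and is user-adjustable.
* PRM scores are relative similarity measures, not concentrations;
  monotone association with composition holds on controlled mixtures (the
  fraction-series tests), but absolute quantification requires calibrated
  unmixing.
* Group-level statistics, segmentation, and display-only filtering are out
  of scope by design; ROI masks are accepted from external tools.
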