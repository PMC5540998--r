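---
title: "Similarity unmixing: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity unmixing: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simi)
```

## The detection model and what SIMI actually estimates

A multichannel detector measures, at every pixel, a vector of intensities
$S = (S_1, \dots, S_n)$ over $n$ spectral channels ordered by ascending
center wavelength. Under the linear detection model each fluorophore $j$
contributes in proportion to its emission signature, so
$S_i = \sum_j a_{ij} F_j$, with the *fingerprint* $a_{\cdot j}$ normalized
to $\sum_i a_{ij} = 1$. Linear unmixing inverts this system for the
abundances $F_j$, which requires $m \le n$ fluorophores and a full-rank
mixing matrix.

Similarity unmixing answers a different question: *which single fluorophore
does this pixel belong to?* The pixel's channel vector is normalized to
$b = S / \sum_i S_i$ and compared against every fingerprint by the squared
difference $R^2_j = \sum_i (b_i - a_{ij})^2$; the smallest score wins. The
normalization makes the decision depend only on channel *ratios*, so the
number of separable fluorophores is limited by fingerprint distinctness,
not by the channel count: three fluorophores are separable on two channels
whenever their two-element fingerprints have pairwise different ratios.

The price is the **one-fluorophore-per-pixel assumption**. SIMI reports
identity and deposits the pixel's intensity into exactly one output
channel; it never estimates fractional abundances. Objects that genuinely
mix signatures (phagocytes carrying engulfed labeled material) are handled
the way a practitioner would: define an extra empirical fingerprint for the
mixed signature, annotated directly on the mixed image
(`fingerprint_from_annotated_region()`), and classify it as its own class.

Because the candidate set is discrete and small, the score is evaluated
exhaustively over all $m$ fingerprints rather than by an iterative
optimizer; for a finite candidate set this returns the global minimum
deterministically.

## Tunable parameters

* `threshold` (counts of total signal; default `"otsu"`): pixels at or
  below it are background (label 0). The Otsu default is computed on the
  total-signal image; see the numerical notes below. An absolute override
  is available for calibrated data.
* `intensity` (`"total"` default, `"max"`): the scalar written into the
  winning fluorophore channel. `"total"` deposits the pixel's summed
  cross-channel signal, which conserves the measured photons exactly
  (the sum over output channels equals the foreground input signal);
  `"max"` deposits the brightest channel's value. Both readings of the
  normalization constant are exposed because either convention is found in
  practice.
* `tie_eps` (default `1e-9` on the score): when the runner-up score is
  within this margin the pixel is flagged ambiguous. Ties resolve to the
  lowest fluorophore index so results are deterministic; downstream code
  can mask flagged pixels instead.
* `median_filter` (default off): an optional 3×3 modal smoothing of the
  label map. It is an extension beyond the per-pixel method and therefore
  disabled unless requested.
* Background estimation (`estimate_background()`): per-channel, never a
  scalar, because detector offsets differ between PMTs. The default is the
  mean of the dimmest 5% of pixels (ranked by total signal); user-ROI and
  explicit vectors are alternatives. Fingerprint extraction uses the
  per-channel *mean* over the foreground mask (a median option exists for
  robustness against debris).

A practical separability diagnostic is `min_pairwise_separation()`, the
smallest $R^2$ between any two fingerprints in a set. `unmix_image()` warns
below 0.02 — classes that close approach each other within roughly one
noise standard deviation at typical two-photon count levels (at 200 total
counts spread over 6 channels the per-element noise on $b$ is about 0.03,
so a squared distance of 0.02 corresponds to a between-class margin of
about 2 standard deviations).

## What the synthetic scenes emulate — and what they do not

`scene_config()`/`simulate_scene()` generate the statistical structure the
method assumes: disk-shaped cells (blob-like at lymph-node imaging scale)
placed without overlap by dart throwing, each emitting with exactly one
fingerprint; per-object brightness drawn lognormally (expression-level
variability; default spread `sdlog = 0.25`) and uniform within an object;
per-channel constant background (default 0.5 counts); Poisson shot noise
plus additive Gaussian read noise (default sd 1 count) clamped at zero.
Default scenes are 128×128 pixels with 30 objects of radius 4–9 px and a
mean total brightness of 200 counts per foreground pixel — the count regime
used throughout the tests. Optional mixed-signature objects emit a stated
convex combination $w\,a_j + (1-w)\,a_k$ and carry the extra class label
$m+1$.

Deliberately *not* modeled: optical blur (PSF), depth-dependent scattering
and attenuation, motion artifacts, autofluorescence gradients, or any
spectral distortion beyond the fingerprint model itself. Passing tests on
these scenes therefore demonstrate the correctness of the classification
machinery and its noise behavior, not robustness to optics-induced model
violations in real tissue — on real data, fingerprints should be measured
in situ precisely because tissue modifies emission spectra nonuniformly.

Two generator choices worth stating. First, class identities are drawn
multinomially from the configured proportions, but by default
(`ensure_all_classes = TRUE`) at least one object of every pure class is
guaranteed when `n_objects >= m`; scenes exist to exercise all classes, and
"every class recovered" is only meaningful when every class is present.
Second, the shipped preset fingerprints (`preset_scenario()`) are synthetic
constructions — dominant-channel signatures with spectral bleed plus one
broad signature — chosen to satisfy a pairwise separation of at least 0.02.
They are not measured emission spectra of any real fluorophore.

## Numerical choices

* **Normalization convention.** Fingerprints and pixel signatures sum to
  one; the normalization constant of a pixel is its total cross-channel
  signal. Weights below $10^{-12}$ (tiny negatives left by background
  subtraction) are clamped to zero before renormalizing, so fingerprints
  are always valid probability vectors.
* **Otsu on variance-stabilized counts.** The background threshold is
  computed by Otsu's method on *square-root transformed* total counts and
  mapped back to the raw scale. On raw Poisson-scale histograms the
  between-class criterion is dragged upward by bright objects and can place
  the threshold above the dimmest cells; the square-root transform
  (approximately variance-stabilizing for Poisson data) makes the
  background/foreground split insensitive to the brightness spread.
* **Residual accuracy.** The vectorized classifier ranks fingerprints with
  the expanded form $\lVert b\rVert^2 - 2\,b^\top a_j + \lVert a_j\rVert^2$
  for speed, then recomputes the winning score in direct form
  $\sum_i (b_i - a_{ij})^2$; the expanded form cancels catastrophically
  near zero, and pure-class pixels should (and do) report exactly 0.
* **Degenerate inputs.** All-zero pixels cannot be normalized and map to
  the background label; an all-background image yields an empty result
  with a warning; a fingerprint set whose members coincide is usable but
  triggers the separability warning. Underdetermined input to the *linear*
  solver is a hard error (not a pseudo-inverse guess) that names SIMI as
  the applicable method — the contrast between the two regimes is part of
  the API contract.
* **Storage.** Intensity images are written as 32-bit IEEE-float TIFF
  (lossless at single precision), labels as 16-bit integer TIFF. The
  detection-filter labels (466/40 … 710/40 nm) are metadata only; no
  computation reads wavelengths.

## Design decisions that were genuinely open

* **Deposited scalar.** Nothing in the similarity rule dictates what
  intensity to write into the unmixed channel. Total signal is the default
  because it conserves measured photons and makes the conservation
  invariant exact; the winning-channel maximum is offered as the
  alternative reading.
* **Tie-breaking.** Lowest index wins, with an explicit ambiguity flag,
  rather than random or unclassified — determinism is worth more than
  symmetry for a per-pixel method, and the flag preserves the information.
* **Hard error for underdetermined linear unmixing.** A minimum-norm
  pseudo-inverse solution would silently return one of infinitely many
  solutions; failing loudly keeps the regimes honest.
* **Evaluation conventions.** Pixel accuracy is computed over
  truth-foreground pixels only (the claims concern labeled compartments);
  background confusion is reported separately in row/column 0. An object's
  modal predicted label decides object-level accuracy, and modal *ties
  count as incorrect* — the conservative choice. A class counts as
  recovered only if every one of its objects is majority-correct.

## Problem sizes used by the tests

The suite runs entirely on generated data: preset scenes of 128×128 pixels
with 30 objects (5–10 seeds per claim), 32×32 random images for
oracle-equivalence checks, 100×100 single-class fields (10⁴ pixels, 20
seeds) for fingerprint-estimation accuracy, and 100 seeds of 50-object
layouts for the multinomial sanity band. These sizes give stable statistics
for every asserted margin while keeping the full suite in the tens of
seconds.

## Known limitations

* No fractional abundances — by design; use the linear baseline when
  `m <= n` and mixtures are expected within pixels.
* No spatial or temporal regularization; stacks are processed plane-wise
  and independently.
* Fingerprints are empirical vectors; the package never derives them from
  published emission spectra, and quantitative results inherit whatever
  bias the reference measurements carry.
* The FRET-style extension (modeling a pixel as a linear combination of a
  donor and acceptor fingerprint and reporting the mixing coefficient) is
  out of scope.
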