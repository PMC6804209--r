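---
title: "Methods: Raman tissue classification, band imaging and texture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman tissue classification, band imaging and texture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsrm)
```

## The problem and the model

Pituitary adenomas must be distinguished from healthy gland tissue during
resection, and their hormonal subtype matters for prognosis. Raman
microspectroscopy resolves this molecularly: each tissue class expresses a
characteristic pattern over twelve diagnostic Raman shifts between 590 and
2945 cm⁻¹ (phenylalanine at 1004 cm⁻¹, nucleic-acid/phospholipid modes at
1093 cm⁻¹, protein/collagen backbone bands, and the CH₂/CH₃ stretching
bands at 2873/2945 cm⁻¹). The analysis chain is: preprocess each spectrum,
reduce dimension by PCA, classify with a 1-nearest-neighbor rule, and — for
line-scan image cubes — slice band images at the diagnostic shifts,
quantify their texture with grey-level co-occurrence matrices (GLCMs), and
compare classes through 2-D image correlation.

`lsrm` implements that chain end to end and pairs it with a synthetic
generator, because the underlying clinical spectra are not distributable.
Every statement a test makes therefore refers to the generator's stated
world, not to clinical data.

## The synthetic generator: what it emulates, what it does not

A class is described by a `band_profile`: pseudo-Voigt peaks (fixed 0.5
Lorentzian fraction — the conventional single-parameter line shape for
condensed-phase Raman bands) at the twelve band positions, with per-class
relative amplitude tiers held in one editable table
(`class_band_tiers`). The tiers encode the qualitative class signatures:

* gland expresses all twelve bands, more weakly below ~1100 cm⁻¹;
* every adenoma subtype has exactly zero amplitude at 1004 cm⁻¹;
* gonadotroph adenoma additionally lacks 1093 cm⁻¹;
* the periosteal layer lacks 590, 658, 1004 and 1093 cm⁻¹ and carries a
  collagen-heavy fingerprint;
* the remaining tier values (low 0.15 … high 1.0) are documented
  **stand-ins**, not measurements: no quantitative per-class amplitudes
  exist to copy. The plurihormonal pattern in particular is invented (its
  spectrum is nowhere described); it was given a band pattern distinct
  from corticotroph during initial design, because a stated world in which
  two classes are near-collinear after per-spectrum normalization would
  contradict the premise that all subtypes are classifiable.

On top of the peaks sit (i) a smooth autofluorescence baseline — by
default a degree-5 polynomial in the *reversed* axis coordinate with
positive coefficients, i.e. decreasing with wavenumber as tissue
autofluorescence does under near-infrared excitation, scaled to twice the
tallest peak; kept strictly below the degree-9 removal fit so removal is
well-posed — and (ii) additive Gaussian noise with sd equal to 5 % of the
tallest peak (Poisson counts available as an option), plus optional
cosmic-ray spikes (rate 0 by default). Replicate spectra differ through a
log-normal amplitude jitter (sd 0.15 on the log scale) drawn per spectrum
and band; stated band absences are never jittered. The default axis is
500–3200 cm⁻¹ at 2 cm⁻¹ spacing.

Cubes follow the line-scan geometry: 20 positions along a 100 µm laser
line (5 µm pitch) × 50 stage steps of 10 µm. Per-band concentration maps
in [0, 1] modulate the peak amplitudes per pixel; available patterns are
uniform, smoothed random fields, and the two-compartment layout in which
the 1331 cm⁻¹ and 1445 cm⁻¹ bands occupy complementary halves — the
configuration that produces the anticorrelated band images and the
magenta/green overlay.

**Not emulated:** instrument physics (CCD quantum efficiency, optical
PSF), absolute intensities, spatial correlation between neighboring
spectra of one biopsy, and biological within-class heterogeneity beyond
the amplitude jitter. A green classification test on this generator
establishes that the pipeline recovers the designed class structure — it
does **not** establish clinical accuracy; the clinical per-class numbers
serve only as a template for what the recovery test asks (≥ 0.95 overall
accuracy at 200 spectra/class).

## Preprocessing: choices and numerical behavior

Stage order is fixed: transmission correction → baseline removal →
Savitzky–Golay smoothing → region cropping → 0–1 normalization. Cropping
is placed *before* normalization so the 0–1 scale reflects only retained
channels; the silent region (1700–2800 cm⁻¹) is cropped by default but
any region list (including none) can be supplied.

**Baseline removal** is the iterative modified polyfit: fit a degree-9
polynomial by least squares, replace the working signal by the point-wise
minimum of signal and fit, refit; stop when the fit's maximum relative
change falls below 1e-6 or after 100 iterations (non-convergence is
flagged, never silently accepted). Two numerical facts matter:

* On smooth peak-free input the converged fit equals the input to within
  tolerance, so the bound "fit ≤ raw signal + tolerance" holds exactly
  there. On *noisy* input any least-squares fit exceeds the signal at
  roughly half the channels by O(noise sd); the min-clip construction
  bounds the fit by the clipped working signal instead, and the converged
  fit settles about one noise quantile *below* the true background. The
  corrected spectrum therefore carries a small uniform positive offset
  (~+9 % of a unit peak at the default noise). Peak heights should be
  read above local background — the package's recovery tests measure
  apex minus the median 40–80 cm⁻¹ off-peak, which brings the median
  recovery error to ~3.6 %.
* A second application of the remover is not a strict no-op: on
  peaks-over-zero input the degree-9 fit finds a small lower-envelope
  polynomial, changing the corrected spectrum at the sub-percent-of-peak
  level (tested at < 2 % of the maximum), not at the 1e-6 fit tolerance.

**Savitzky–Golay** uses the window-21/order-3 least-squares convolution
on a uniform axis; edges are handled by asymmetric full-window fits, so
polynomials up to the filter order pass through *exactly*, including at
the boundaries, and the output length equals the input length. Non-uniform
axes are linearly resampled to a uniform grid first (flag-controlled);
detector pixels are not uniform in cm⁻¹, so axis calibration alone does
not guarantee uniformity.

The batched matrix path (`preprocess_set`, `preprocess_cube`) and the
single-spectrum path share one engine, and each spectrum's baseline
iteration is frozen at its own convergence check — a spectrum preprocessed
inside a batch is bit-for-bit comparable to the same spectrum preprocessed
alone.

Constant spectra cannot be 0–1 normalized; the default is an error, with
an opt-in all-zeros fallback (flagged per spectrum) for batch robustness.

## Classification

PCA is the mean-centered orthogonal decomposition with no variance
scaling; the component count is the smallest m whose cumulative explained
variance reaches the threshold (default 0.95). Loading signs are fixed by
making each loading's largest-magnitude coefficient positive, so scores
are reproducible across platforms. The kNN uses k = 1, Euclidean distance,
equal weights; exact distance ties resolve to the lowest training index —
a documented deterministic rule rather than a random draw.

Per-class "accuracy" is class recall (correct members / class size): the
only reading under which one number per class plus a single overall
accuracy is coherent. The holdout split (default 25 %) is stratified per
class at the spectrum level by default; a biopsy-level grouped split is
provided because spectrum-level splitting lets near-identical neighboring
pixels of one biopsy leak across partitions — with real cubes the grouped
split is the honest choice, and both are reported with their split
metadata. Whether a real study's holdout was grouped is not asserted
either way.

## Imaging and texture

Band images average the channels within ±5 cm⁻¹ of the band center by
default (half-window 0 selects the single nearest channel); both modes
are exposed since either convention is defensible. The first cube axis
(laser line) renders vertically. Overlay scaling is per-image min-max; a
constant image maps to full brightness if positive and to dark otherwise,
so a uniformly "on" band reads as present.

GLCMs use 8 grey levels binned linearly between image minimum and maximum
(so features are shift-invariant), ordered (non-symmetric) pairs, and the
four unit offsets (0,1), (−1,1), (−1,0), (−1,−1) for 0°/45°/90°/135°
with row indices increasing downward. Features are the mean over offsets
and the median over images per (class, band) — the "mean over offsets,
median over images" resolution of an ambiguous aggregation order, chosen
and flagged here. An undefined correlation (degenerate marginal, e.g. any
constant image) propagates as `NA` and is excluded from aggregation;
it is never coerced to 0 or 1. `corr2` is the Pearson coefficient of the
mean-centered flattened images; the class comparison matrix correlates
each class against the gland reference at each band after center-cropping
all images to the common minimal shape (all-vs-all mode available; which
image of each class enters the comparison is configuration, not a claim).

## Tolerances and degenerate inputs

* Baseline: relative tolerance 1e-6, ≤ 100 iterations, convergence
  checked every 5 iterations against the previous iterate.
* PCA is checked against a brute-force covariance eigendecomposition at
  |Δratio| < 1e-10; reconstruction round-trips at 1e-8.
* The generative-mean check accepts ≤ 1 % of channels outside 3 standard
  errors (with 1351 channels and 1000 draws, ~0.27 % are expected outside
  by chance, so "every channel within 3 SE" would be a test of luck, not
  correctness) and none outside 6 SE.
* Zero spectra, empty profiles, constant images, degenerate GLCM
  marginals and single-biopsy classes all have defined, tested behavior
  (exact zeros, `NA` flags, or informative errors — never silent
  coercion).

## Known limitations

* Amplitude tiers are stand-ins; conclusions about class separability are
  statements about the generator, not about tissue.
* The min-clip baseline bias under noise (above) is inherent to the
  algorithm family; quantitative peak work should use local-background
  peak heights.
* Broad overlapping bands (the CH-stretching pair) make "largest
  amplitude" and "highest apex" diverge; apex-based checks use
  well-separated bands.
* HDF5 and TIFF interchange are replaced by a versioned plain-text cube
  format and PNG rendering; the in-memory contracts are unchanged.
* No despiking beyond the optional cosmic-spike generator; no classifiers
  other than kNN; no spectral unmixing.
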