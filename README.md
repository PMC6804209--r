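# lsrm — line-scan Raman microspectroscopy analysis of pituitary tissue

`lsrm` implements a label-free Raman diagnostic workflow for pituitary
tissue, aimed at spectroscopists and analysts who need to discriminate
pituitary gland from adenoma subtypes (corticotroph, gonadotroph,
somatotroph, plurihormonal, null cell) and from the collagen-rich
periosteal layer. Because clinical biopsy spectra cannot be redistributed,
the package ships a first-class synthetic generator that emulates the
class-specific band signatures, so the complete pipeline is reproducible
and testable offline.

## What it computes

1. **Preprocessing** of raw spectra covering 500–3200 cm⁻¹: system
   transmission correction; autofluorescence removal by an iterative
   degree-9 polynomial fit (fit → point-wise minimum → refit, to
   convergence); Savitzky–Golay smoothing (window 21, order 3); cropping to
   the fingerprint (500–1700 cm⁻¹) and CH-stretching (2800–3000 cm⁻¹)
   regions; per-spectrum 0–1 normalization.
2. **Classification**: mean-centered PCA keeping the smallest number of
   components explaining ≥ 95 % of variance, then a *fine* kNN (k = 1,
   Euclidean distance, equal weights) evaluated with a stratified 25 %
   holdout. Reported per class as recall and overall as trace/total of the
   confusion matrix.
3. **Hyperspectral imaging**: per-pixel preprocessing of
   (line × step × wavenumber) cubes, band-image extraction at the 12
   diagnostic Raman shifts {590, 658, 874, 939, 1004, 1093, 1254, 1331,
   1445, 1663, 2873, 2945} cm⁻¹, and two-band magenta/green overlays.
4. **Texture analysis**: grey-level co-occurrence matrices (8 levels,
   offsets at 0°/45°/90°/135°) with the four Haralick statistics

   contrast = Σᵢⱼ p(i,j)(i−j)², correlation = Σᵢⱼ p(i,j)(i−μᵢ)(j−μⱼ)/(σᵢσⱼ),
   energy = Σᵢⱼ p(i,j)², homogeneity = Σᵢⱼ p(i,j)/(1+|i−j|),

   aggregated as mean over offsets and median over images per
   (class, band); plus 2-D Pearson correlation coefficients (`corr2`)
   between class band-images and the gland reference.

Key class signatures encoded by the generator: every adenoma subtype lacks
the 1004 cm⁻¹ phenylalanine band; gonadotroph adenoma additionally lacks
1093 cm⁻¹; the periosteal layer lacks 590, 658, 1004 and 1093 cm⁻¹; gland
expresses all twelve bands.

## Worked example

```r
library(lsrm)
run <- run_full_analysis(run_config(n_spectra_per_class = 50L, seed = 1L))
print(run$classification)
```

```
<classification_report> n = 84
overall accuracy: 0.964
per-class accuracy (recall):
 corticotroph         gland   gonadotroph     null_cell    periosteal
        0.833         1.000         0.917         1.000         1.000
plurihormonal   somatotroph
        1.000         1.000
```

84 spectra (25 % of 7 × 48 after rounding) were held out; 16 principal
components reached the 95 % variance threshold. The lower corticotroph /
gonadotroph recalls mirror their spectral similarity; gland and periosteal
layer separate perfectly — the qualitative pattern expected from tissue
Raman data at this problem size.

```r
round(run$correlation[, c("1004", "1331", "1445", "2945")], 2)
```

```
              1004  1331  1445  2945
gland         1.00  1.00  1.00  1.00
corticotroph -0.15  0.06  0.06 -0.18
gonadotroph   0.01  0.24  0.15  0.04
somatotroph  -0.04 -0.20 -0.22 -0.08
null_cell     0.05 -0.03  0.02  0.23
periosteal    0.02 -0.06 -0.01 -0.10
```

Rows are class band-images correlated against the gland reference at the
same band (gland vs itself is 1 by construction). `run$texture` holds the
72-row (6 classes × 12 bands) Haralick summary, and `run$overlay` the
1331/1445 cm⁻¹ magenta/green composite of the somatotroph cube, which has
anticorrelated compartments for these two bands.

## Command line

`inst/exec/lsrm-cli.R` wraps the package for shell use:

```sh
Rscript inst/exec/lsrm-cli.R simulate --kind spectra --size small --seed 1 --dir out/
Rscript inst/exec/lsrm-cli.R classify --input out/spectra_small_seed1.csv --out report.json
Rscript inst/exec/lsrm-cli.R run-all  --seed 1 --out-dir out/run
```
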