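# fibrilquant

Quantification of fibrillar collagen organization in second-harmonic
generation (SHG) microscopy, plus single-hit limiting-dilution analysis of
tumor-initiating cell frequency.

## What it is for

Studies of the tumor microenvironment routinely ask whether the stroma has
been remodeled: is there more fibrillar collagen near the tumor–stromal
interface, is the fiber network more organized, are the fibers more
aligned — and does that remodeling change the frequency of tumor-initiating
(cancer stem) cells measured functionally by limiting-dilution
transplantation? `fibrilquant` is a reproducible R implementation of that
entire measurement chain, for imaging scientists and tumor biologists who
today run it as a mix of ImageJ macros and web tools:

* **Coverage** — percent area covered by SHG signal after a single global
  threshold applied across all study images, per image and by imaging
  depth (with peak-coverage summary), optionally restricted to an ROI or
  to the interface band within a configurable distance (default 200 μm) of
  a compartment mask.
* **GLCM texture** — gray-level co-occurrence matrices and the Haralick
  correlation as a function of pixel offset,
  `corr(P) = Σᵢⱼ (i−μᵢ)(j−μⱼ) P[i,j] / (σᵢσⱼ)`,
  summarized by the area under the correlation–distance curve and the
  half-decay distance; slower decay = a more organized, longer-range
  correlated fiber network.
* **Orientation** — cubic B-spline image gradients, structure tensors
  `J = G_σ * (∇I ∇Iᵀ)`, per-pixel orientation
  `θ = ½·atan2(2Jxy, Jxx−Jyy) + 90°` and coherency, axial orientation
  histograms with **peak alignment** (mode, degrees) and **alignment
  frequency** (mass within ±Δ of the peak, Δ = 10° default).
* **Limiting dilution** — the single-hit Poisson model
  `P(take | dose d) = 1 − exp(−f·d)` fitted by maximum likelihood in
  log f (equivalently a binomial GLM with complementary log-log link and
  offset log d), with profile-likelihood 95% CIs, ELDA-style handling of
  all-negative/all-positive assays, "1 in N" reporting, and a
  likelihood-ratio group test.
* **Synthetic phantoms** — an SHG fiber-scene generator (von Mises axial
  orientations, Gaussian-profile curvilinear fibers, PSF + photon/read
  noise) with exact ground truth for coverage, peak angle and alignment,
  so every statistic above is testable without external data.
* **Batch runs** — `run_study()` orchestrates image sets and groups,
  applies the field's comparison tests (equal-variance t, Mann–Whitney,
  Kruskal–Wallis, Fisher's exact) and writes deterministic CSV/JSON
  outputs with full parameter provenance.

## Worked example

```r
library(fibrilquant)

# a synthetic 320 x 320 um SHG field: 160 fibers peaked at 30 deg, kappa = 8
spec  <- fiber_scene_spec(height_px = 256, width_px = 256, pixel_size_um = 1.25,
                          n_fibers = 160, peak_angle_deg = 30, kappa = 8, seed = 1)
scene <- generate_fiber_scene(spec)
scene
#> <synthetic_scene> 256 x 256 px, 160 fibers, coverage 0.199, peak 30 deg, alignment 0.591 (delta 10 deg)

coverage(scene$image, pooled_otsu_threshold(scene$image))
#> <coverage_result> 21.715% (14231 / 65536 px, threshold 0.4735822)

analyze_orientation(normalize_intensity(scene$image, "percentile"))$histogram
#> <orientation_histogram> peak 28.5 deg, alignment frequency 0.684 (delta 10 deg, coherency-weighted, 44777 px)

correlation_decay(normalize_intensity(scene$image, "percentile"),
                  glcm_config(distances_px = 1:24))
#> <glcm_decay> phantom: 24 offsets (1..24 px), corr[1] = 0.801, auc = 0.112, half-decay = 2.6 px
```

The coverage (21.7% measured on the noisy image vs 19.9% ground truth at
the footprint definition), the recovered peak (28.5° vs the true 30°
mode) and the alignment frequency (0.68; pixel-level readouts run above
the 0.59 centerline truth at this density — see the methods vignette) are
all computed from the one global threshold, the structure-tensor field and
the angle-averaged GLCM curve respectively.

Limiting-dilution analysis of a bundled synthetic assay (two groups, four
doses, 10 recipients per dose):

```r
tabs <- read_dilution_table(system.file("extdata", "synthetic_dilution_example.csv",
                                        package = "fibrilquant"))
fit_single_hit(tabs$hh)
#> Single-hit limiting-dilution fit (hh)
#>   frequency: 0.00449  (1 in 223)
#>   95% CI: 0.0024 .. 0.008091  (1 in 124 .. 1 in 417)

cmp <- compare_frequencies(tabs$ctrl, tabs$hh)
#> LRT: chisq = 11.18, p = 0.0008
```

A thin command-line wrapper with `synth`, `coverage`, `glcm`, `orient`,
`lda` and `run` subcommands is installed at
`system.file("cli", "fibrilquant.R", package = "fibrilquant")`.

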