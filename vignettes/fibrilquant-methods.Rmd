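---
title: "Quantifying fibrillar collagen organization: models and design choices"
author: "fibrilquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibrillar collagen organization: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilquant)
```

## Scope

Second-harmonic generation (SHG) microscopy images fibrillar collagen
label-free: the non-centrosymmetric structure of assembled collagen I/III
fibers produces a strong second-harmonic signal, so pixel intensity marks
fibers directly. In studies of the tumor microenvironment, three readouts of
the collagen matrix are standard: how much of the field is covered by
fibers (abundance/density), how far the signal stays correlated across the
field (organization), and how strongly fibers share a common direction
(alignment). `fibrilquant` implements all three — percent-area coverage
after global thresholding, gray-level co-occurrence matrix (GLCM)
correlation decay, and structure-tensor orientation statistics — plus the
single-hit Poisson limiting-dilution model used to estimate the frequency
of tumor-initiating (cancer stem) cells from transplantation assays, the
functional readout that stromal collagen remodeling is typically tested
against.

Because raw tissue images are rarely deposited, the package ships a
synthetic fiber-phantom generator with exact ground truth; every statistic
in the package is validated against it.

## Coverage

An intensity image is binarized at a single global threshold `t`: pixel
positive iff intensity strictly exceeds `t`. Coverage is the percentage of
ROI pixels that are positive. The strict comparison means an all-zero image
has 0% coverage at threshold 0, and makes the binarization of the
generator's noiseless scene reproduce its ground-truth mask bit for bit.

The threshold is a study-level constant: one value applied to every image
of a study, as is standard practice when comparing groups. Because a
manual choice is not reproducible, `pooled_otsu_threshold()` offers a
deterministic stand-in: Otsu's criterion applied to the pooled intensity
histogram of all study images, then applied globally. No morphological
cleanup (despeckling, hole filling) is applied — the statistic is a pure
function of the thresholded image.

For z-stacks, `coverage_by_depth()` reports the per-slice profile (depth =
slice index times the slice spacing) and its maximum, the peak-coverage
summary commonly reported for depth series.

## GLCM correlation decay

The GLCM at offset `(d, theta)` is the normalized joint histogram of
quantized gray levels at pixel pairs separated by that offset. We report
the Haralick correlation feature

$$\mathrm{corr}(P) \;=\; \frac{\sum_{ij}(i-\mu_i)(j-\mu_j)P_{ij}}{\sigma_i\,\sigma_j},$$

with marginal means and standard deviations of `P`, as a function of the
offset distance. Slow decay of this curve with distance indicates a
long-range correlated, organized fiber network; fast decay a disordered
one.

Conventions, all fixed and echoed into outputs:

* angle-to-offset map: 0° = +column, 90° = −row; diagonal offsets step the
  Chebyshev distance `d` in both axes;
* quantization: uniform bins over the ROI's intensity range, per image —
  the correlation feature is invariant to affine intensity maps, so this
  removes per-image gain differences;
* symmetric accumulation by default (`P = P^T` exactly);
* defaults: 64 gray levels, distances 1–64 px, the four principal angles
  averaged.

Two scalar summaries are reported because the field's figures plot the
curve without defining a scalar: the area under the correlation–distance
curve (trapezoidal, normalized by the distance span) and the half-decay
distance (first offset at which the correlation falls to half its value at
the smallest offset, linearly interpolated, `Inf` if never reached).

One physical caveat that the package's own phantom experiments expose: the
*angle-averaged* curve mixes decay along fibers (slow, set by fiber length
and network continuity) with decay across fibers (fast, set by fiber width
and the point-spread function). In the average, the across-fiber term
dominates the early decay, so the half-decay distance of the averaged curve
barely distinguishes aligned from isotropic networks. Measured *along the
dominant fiber axis* (a single-angle `glcm_config`), both summaries
separate aligned from isotropic phantoms decisively (half-decay ~20 px vs
~3 px at the package's phantom defaults). When a study's purpose is an
organization contrast, configure the angles accordingly; the default
remains the four-angle average for general texture description.

## Structure-tensor orientation analysis

Spatial derivatives are computed by representing the image in a cubic
B-spline basis (recursive prefilter, pole $z = \sqrt3 - 2$, mirror
boundary conditions) and differentiating the spline analytically at pixel
centers. This reproduces derivatives of polynomial images up to degree 3
exactly in the interior; like any recursive spline filter it carries a
boundary layer decaying as $|z|^k$ with distance `k` from the border,
which is why validity masks exclude a margin near the frame.

The structure tensor is the Gaussian-windowed average (s.d.
`window_sigma_px`, mirror boundaries) of the gradient outer product. Per
pixel, the dominant orientation is
$\tfrac12\,\mathrm{atan2}(2J_{xy},\,J_{xx}-J_{yy})$ — the gradient
direction — and the *structure* (fiber) orientation is perpendicular to it.
Angles are reported in degrees counter-clockwise from the +column axis in
the axial range (−90°, 90°] (θ and θ+180° are the same fiber direction).
Coherency, $\sqrt{(J_{xx}-J_{yy})^2 + 4J_{xy}^2}\,/\,(J_{xx}+J_{yy})$, is
0 for isotropic texture and 1 for a rank-one (perfectly oriented) tensor.

Pixels enter the orientation histogram only if they pass an energy gate
(tensor trace at or above the 25th ROI percentile by default), a coherency
gate (0.2 by default — this masks the isotropic pixels), and a border
margin of `3 * window_sigma_px`. The histogram over (−90°, 90°] uses 1°
bins by default and coherency weighting; the **peak alignment** is the
center of the maximal bin (ties broken toward the smaller angle, for
determinism), and the **alignment frequency** is the histogram mass in the
half-open axial window of total width 2Δ around the peak (Δ = 10° by
default, exposed as a first-class parameter). Under a uniform orientation
distribution the alignment frequency therefore tends to 2Δ/180 ≈ 0.111.
"Frequency of fiber alignment" has no standard formal definition; this
operationalization is the package's documented choice.

Two practical notes from the phantom validation:

* The effective sample size of the peak estimate is the number of fibers,
  not the number of pixels — pixels within a fiber share one orientation.
  At low concentration (κ ≈ 2) the max-bin peak of a single 320-μm field
  wanders by ±2–4°. Pooling the histograms of several fields per sample
  (`pool_orientation_histograms()`), as multi-area acquisition protocols
  do, restores degree-level accuracy; the package's validation pools three
  fields per sample.
* Crossing fibers bias pixel orientations toward the locally dominant
  direction, so at high fiber density the measured alignment frequency
  exceeds the centerline ground truth. The effect is conservative for
  group contrasts (it sharpens aligned scenes) but should be kept in mind
  when interpreting absolute alignment frequencies.

Distribution-level comparisons between two orientation samples use the
Mann–Whitney U test on absolute axial deviations from the pooled peak,
two-sided with continuity correction.

## Interface band

Stromal readouts are commonly restricted to a band within a fixed distance
(200 μm by default) of a compartment boundary, e.g. the tumor–stromal
interface defined by a fibroblast mask. `interface_band()` returns the
pixels outside the compartment whose Euclidean distance (center-to-center,
physical units) to the nearest compartment pixel is at most the band depth.
The distance transform is exact (validated against all-pairs distances);
pixel coordinates are 0-based `(row, col)` and anisotropic pixels are
rejected rather than silently averaged.

## The synthetic fiber phantom

`generate_fiber_scene()` renders `n_fibers` curvilinear fibers on a
constant background over a field of view of 320 × 320 μm by default (512 ×
512 px at 0.625 μm/px, a typical two-photon acquisition geometry). Each
fiber:

* draws its axial angle from a von Mises distribution on the *doubled*
  angle 2θ (the standard treatment of axial data; κ = 0 is isotropic,
  sampling by the Best–Fisher envelope method);
* draws its length from a gamma distribution (mean 100 μm, s.d. 30 μm by
  default) and walks from a uniform start point with a stationary AR(1)
  angular jitter (`wiggle`, innovation s.d. 2°/step, correlation 0.9) —
  bounded waviness rather than an unbounded random walk, so the fiber's
  direction stays near its sampled angle;
* is rasterized as a polyline with a Gaussian intensity cross-section
  whose FWHM is `fiber_width_um` (2.5 μm by default), by dense Gaussian
  stamping (anti-aliased by construction); fibers may leave the frame, with
  no periodic wrap.

The scene is then convolved with a Gaussian PSF (σ 0.6 μm) and corrupted
by Poisson-scaled photon noise and additive Gaussian read noise, both
optional. Ground truth — footprint mask, coverage, peak angle, alignment
fraction, centerline segments — is taken from the **pre-PSF, pre-noise**
rasterization: the truth mask is defined by the same strict thresholding
operation the coverage module applies (at background + half the fiber
intensity), so measured coverage on the noiseless scene equals the truth
*exactly*, with no blur-dependent tolerance. The scene's
`true_peak_angle_deg` is the nominal mode of the sampling distribution;
`true_alignment_fraction` is the fraction of centerline segments within ±Δ
of it (for κ = 0 this tends to 2Δ/180).

Randomness is split into per-fiber substreams derived from the scene seed
and the fiber index: increasing `n_fibers` appends fibers without
disturbing existing ones (making coverage exactly monotone in fiber
count), and `generate_stack()` reuses one fiber stream across slices so a
depth-density profile selects a prefix of the same fibers — emulating
fibers that persist across depth — which makes per-slice coverage exactly
monotone in the profile and a single-slice stack bit-identical to the
plain scene.

What the phantom does **not** emulate: 3D fiber geometry and projection,
polarization dependence of SHG, realistic fiber-bundle morphology
(branching, bundling, crimp), spatially varying background, tissue
autofluorescence, or detector artifacts. Passing phantom validations
therefore demonstrates that the *estimators* are correct and calibrated on
images whose statistical structure is known — not that any particular
tissue result is reproduced. Fiber width/intensity/density statistics of
real stroma are not claimed; the defaults are documented free parameters.

## Single-hit limiting-dilution model

A limiting-dilution transplantation assay doses `d` cells into `n`
recipients per dilution and scores tumor takes `x`. Under the single-hit
Poisson model, each cell initiates independently with probability `f` (the
active-cell frequency), so

$$P(\text{take}\mid d) = 1 - e^{-f d},$$

a binomial GLM with complementary log-log link and offset log d.
`fit_single_hit()` maximizes the binomial log-likelihood in log f by a
bracketed root of the score (the likelihood is unimodal in log f, which
avoids link-function edge cases); the result matches the closed form
$\hat f = -\ln(1-x/n)/d$ for a single dose and the `glm()` cloglog fit to
better than 1e−6 relative, and rescaling all doses by `c` rescales
$\hat f$ by `1/c` exactly. The 95% CI comes from the profile likelihood
(χ²₁-based), with a Wald fallback in log f if a profile root is not
bracketed. Frequencies are displayed as "1 in N" with N rounded to the
nearest integer.

Assays with no takes at all, or takes in every recipient, carry no
two-sided information: they are flagged (`all_negative` / `all_positive`)
and reported with a one-sided 95% likelihood bound (for an all-negative
assay this reduces to $f_{\mathrm{up}} = -\ln(0.05)/\sum_d n_d d$). Group
comparisons use the likelihood-ratio test of a shared versus
group-specific frequency (1 df). No overdispersion or frailty extension is
fitted — the single-hit model is the estimand. Simulation at the scale of
published tumor-propagating-cell frequencies (1 in ~400, four doses, 24
recipients per dose) shows 93–97% profile-CI coverage and a calibrated
LRT (validated in the test suite).

## Group statistics

`compare_groups()` mirrors the conventions used in this literature: scalar
per-image metrics between two groups by unpaired two-sided t test with
equal variance; orientation distributions by Mann–Whitney; three or more
groups by Kruskal–Wallis; penetrance counts by Fisher's exact test. No
multiple-testing correction is applied (matching common practice in the
figures this pipeline reproduces); the choice of test is recorded in every
output row.

## Determinism and provenance

`run_study()` derives every output from the configuration and a single
seed: reruns produce byte-identical CSVs. Outputs embed the md5 hash of
the canonical YAML rendering of the configuration, the package version,
and all analysis parameters; per-image failures are logged and counted,
never silently dropped.

## Numerical choices and degenerate inputs

* Strict `>` in thresholding; ties in the histogram peak break toward the
  smaller angle; `which.max` tie-breaking is therefore deterministic.
* Constant textures raise a degenerate-texture error from the GLCM
  correlation (marginal variance 0) rather than returning NaN.
* Empty ROIs, empty orientation selections, all-true/all-false
  compartment masks, offsets with no pixel pairs, and boundary dilution
  tables all raise named errors (`fq_*` condition classes).
* The B-spline prefilter truncates its causal initialization at |z|^K <
  1e−14; profile-likelihood roots are located to 1e−11 in log f.
* Test problem sizes: phantom validations use 256–320 px fields at 1.25
  μm/px (320–400 μm fields of view) with 60–500 fibers, three pooled
  fields per orientation sample, 500-replicate calibration loops for the
  dilution model and 1000–2000 for the test-calibration checks.

## Known limitations

* 2D analysis only; z-stacks are handled slice-wise for coverage depth
  profiles, not as volumes.
* Anisotropic pixels are rejected, not resampled.
* The phantom's realism limits are listed above; in particular, absolute
  alignment frequencies at high fiber density overestimate centerline
  truth.
* The GLCM gray-level count, offsets and scalar summary used by any
  particular published figure are rarely reported; results should state
  the configuration (the package echoes it into all outputs).
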