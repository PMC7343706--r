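---
title: "Pixel-wise plaque tissue characterization in intravascular OCT: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-wise plaque tissue characterization in intravascular OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octplaq)
```

## The problem

Intravascular optical coherence tomography (OCT) resolves the superficial
~1 mm of the arterial wall at ~15 µm, enough to distinguish the three plaque
components that drive rupture risk: fibrous tissue (homogeneous, bright),
calcification (sharply delineated, signal-poor interior with bright rims) and
lipid (strongly attenuating, diffuse). Reading these maps by eye is slow and
subjective; `octplaq` implements an automated pixel-wise pipeline — lumen
segmentation, physical optical-parameter inversion, texture description, and
random-forest classification — together with the statistics needed to
evaluate it, and a forward-model phantom simulator that supplies ground truth
for every stage.

## Signal model and attenuation inversion

The detected A-line intensity is modeled as a single-scattering Lambert–Beer
decay modulated by the imaging system:

$$ I(r) = I_0\; T(r)\; \hat{s}(r)\; e^{-\mu_t (r - r_\mathrm{entry})}, $$

with the confocal axial point spread function
$T(r) = [((r - z_0)/z_R)^2 + 1]^{-1/2}$ (beam waist $z_0$, Rayleigh length
$z_R$) and Gaussian roll-off
$\hat{s}(r) = \exp[-((r - z_C)/z_W)^2]$ (scan center $z_C$, half width
$z_W$). Taking logs and subtracting $\log T$ and $\log \hat{s}$ linearizes
the model; ordinary least squares of the corrected log signal on depth gives
$\hat{\mu}_t = -\text{slope}$ (mm⁻¹) and the intercept $\log I_0$, the
backscatter proxy. Backscattering proper, $\mu_b = I_0 / I'$, is computed
only when the user supplies the locally available intensity $I'$, for which
no measurement recipe exists within the data itself; the feature stack
therefore carries $(\mu_t, \log I_0)$ as its two optical features.

Two conventions are fixed deliberately:

* **Single-$\mu_t$ slope.** The forward simulator and the inverse fitter use
  the same $e^{-\mu_t r}$ convention, so the pipeline is self-consistent.
  Whether a physical round-trip factor of 2 belongs in the exponent is a
  calibration question that does not affect classification (it rescales
  every estimate equally); it is documented here rather than resolved.
* **Entry-anchored depth.** $r$ counts from the tissue entry point of each
  ray (the lumen boundary), not from the catheter, so the fitted intercept
  is clean: on noiseless model signals the fit recovers $(\mu_t, \log I_0)$
  to machine precision for any parameter combination — the package's central
  oracle test.

Per-pixel maps are produced by sliding a window of physical length 0.25 mm
(default; ~50 px at 5 µm, ~25 px at 10 µm — the minimum meaningful window is
3 px) along each A-line over the analysis band
$[\text{boundary}, \text{boundary} + 1\ \text{mm})$, the superficial band
in which annotation is clinically meaningful. Each pixel takes the fit of
the window centered on it; edge pixels take the nearest fully-inside
window. Pixels at or below the noise floor — the 1st percentile of
intra-lumen intensities — are masked out of fits; the rare window with
fewer than three valid points inherits the nearest valid fit along its
A-line.

## Lumen segmentation

The boundary is the closed path (one depth per A-line) minimizing the summed
edge cost under the smoothness constraint $|r_{i+1} - r_i| \le s$ (default
$s = 2$ px/A-line), solved by dynamic programming. Choices the method leaves
open and how they are fixed here:

* **Edge cost**: negative axial gradient of a 3×3 median-filtered copy of
  the image (dark-to-bright transitions), which suppresses speckle without
  displacing edges; the cost is linear in intensity, so the optimum is
  invariant to global intensity scaling.
* **Circular closure**: the DP is solved once per candidate start column —
  every column when the image is at most 16 columns wide (making the
  small-instance exhaustive-search equality test exact), otherwise one
  representative (lowest first-row cost) from each of 8 coarse radius
  buckets — keeping the lowest-cost closed path. Ties break toward the
  smaller radius.
* **Guide-wire shadow**: A-lines are summarized by log mean intensity
  (robust to order-of-magnitude brightness differences between tissue
  sectors); the longest contiguous circular run at least 3 A-lines long
  falling 3 MADs below the median is flagged, and flagged A-lines take
  radii interpolated between their non-shadowed neighbors.

## Texture features

All texture features are computed in an 11×11 px window centered on the
pixel (default; ~55–110 µm, small relative to the 1 mm band), with circular
wrap across the angular seam and clipping at depth edges. Quantization for
the co-occurrence and gray-tone-difference features uses 32 levels anchored
to the whole image's min–max, which keeps small-window matrices
well-populated and makes the features invariant to global intensity
offsets.

* **FOS (5)**: population mean, variance, median, skewness, kurtosis
  (standardized central moments; zero by convention on flat windows). Five
  features including the median are carried, matching the feature table
  used for the ablation experiments.
* **GLCM (7)**: symmetric normalized co-occurrence at distance 1 for angles
  0°, 45°, 90°, 135°; correlation, contrast, dissimilarity, energy, entropy
  (bits), homogeneity and maximum probability are computed per angle and
  averaged, keeping the feature count at seven.
* **NGTDM (5)**: Amadasun–King coarseness, contrast, busyness, complexity
  and strength over 3×3 neighborhoods (center excluded), with
  $\varepsilon = 10^{-12}$ guarding empty denominators; "texture length" in
  the source feature table is read as strength. Note that Amadasun's
  busyness *decreases* as a fixed spatial pattern grows in amplitude (its
  denominator is the tone-weighted spread); the property tests assert the
  actual monotone behavior of the standard definitions.
* **FD (4)**: differential box counting at scales {2, 3, 4, 5}; the window
  is tiled by $s \times s$ columns, the box height is $s\,G/M$ ($G$ = gray
  range anchored at the global minimum, $M$ = window side), and the
  emitted features are the four per-scale log box counts, whose
  least-squares slope against $\log(1/s)$ estimates the fractal dimension
  (exactly 2 on flat surfaces when $s \mid M$).
* **RP (2)**: depth in pixels from the lumen boundary (`x`) and A-line
  index (`y`). Anchoring depth at the boundary makes the position feature
  geometry-covariant rather than catheter-centric.

The per-pixel sweep is implemented in compiled code; unit tests pin it to
the single-window R reference functions and to independent brute-force
enumerations (exact to double rounding, tolerance 1e-12).

## Classification

A random forest (100 trees, 5 of the 25 features tried per split —
$\lfloor\sqrt{25}\rfloor$ — seeded and hence reproducible) performs the
pixel-wise classification. Calcified pixels are typically the rarest class,
so balanced stratified sampling (equal per-class bootstrap sizes) is on by
default. Ties in the vote argmax break by the fixed class order fibrous <
calcified < lipid.

## Evaluation conventions

Pixel-wise metrics are computed over pixels the ground truth labels as
tissue. Sensitivity and specificity are standard one-vs-rest. The
*per-class accuracy* reported alongside is the per-class recall computed
per image and averaged over images; published per-class "accuracy" values
in this literature are sometimes below both sensitivity and specificity,
which the standard one-vs-rest binary accuracy cannot produce, so both
notions are emitted under unambiguous names (`accuracy`,
`accuracy_binary`). Cross-validation groups whole images (never splitting
an image across folds; 50 images → 10 folds of 5), supports the six
feature-set ablations (OP+RP, FOS+RP, GLCM+RP, NGTDM+RP, FD+RP, ALL) and
reports mean, SD and median accuracy over folds; a patient-level holdout
(default 24 train / 7 test patients) is provided separately. Annotation
agreement uses ICC(A,1) — two-way random effects, absolute agreement,
single measurement, with the F-based 95% CI — plus Bland–Altman bias and
limits of agreement and OLS regression of reader 2 on reader 1. The ICC
model form is a choice (the convention in reader-agreement studies);
one-way and average-measure variants are out of scope.

## The phantom simulator

Real annotated pullbacks of carotid plaque are not publicly distributable,
so validation uses a forward-model phantom: annular tissue sectors (each
≥ 1 mm thick so the analysis band stays inside tissue) around a smooth
harmonic lumen, rendered through exactly the signal model above with
tissue-specific $(\mu_t, I_0)$, multiplied by per-tissue texture fields
(1 + amplitude × Gaussian-smoothed unit-variance noise), a bright 2-px rim
on calcified regions (emulating their sharply demarcated borders), a
guide-wire shadow sector suppressed to the noise floor, and unit-mean
gamma speckle with $L$ looks (default $L = 4$, fully developed speckle
after modest frame averaging). Intensities are rounded to 16-bit counts so
datasets round-trip losslessly through TIFF.

Default tissue parameters are representative of 1300 nm intravascular OCT:
fibrous $\mu_t = 3.0$ mm⁻¹ with homogeneous bright backscatter, calcified
$\mu_t = 5.5$ mm⁻¹ with low backscatter and strongly heterogeneous
texture, lipid $\mu_t = 9.0$ mm⁻¹ with bright backscatter. The validation
suite uses 10 synthetic patients × 5 frames (90 A-lines, 10 µm axial
spacing); geometry (radius, sector layout, wall thickness) varies between
patients, realizations vary between frames, and tissue optics are fixed
study conditions.

What the phantom does **not** emulate — and hence what passing tests do
not show about real data: blood and saline flush artifacts, catheter sheath
reflections, non-uniform rotational distortion, multiple scattering and
depth-resolved attenuation structure within a tissue, histology
co-registration error, and the label noise of human annotation. Phantom
recall (≈ 90–99% per class under the defaults) is accordingly an upper
bound sanity check of the pipeline's mechanics, not a claim about clinical
accuracy.

## Numerical choices and degenerate inputs

* Zero-variance windows: skewness/kurtosis 0, GLCM energy 1/entropy 0,
  NGTDM coarseness $1/\varepsilon$, one box per FD column.
* Non-positive intensities are masked before the log transform; an
  all-masked profile is an error ("no fit support").
* A uniformly zero image yields an empty guide-wire mask, not an error.
* Determinism: every stochastic stage (phantom, forest, fold shuffle,
  sampling) is seeded; equal seeds give bit-identical rasters and CSVs.

## Known limitations

Single-scattering inversion biases $\mu_t$ where multiple scattering is
strong (deep lipid); the sliding-window fit smears estimates across tissue
transitions within half a window; the DP cost assumes the lumen is darker
than the wall (a blood-filled lumen would need preprocessing); and the
forest is trained per study — no pretrained model ships with the package.
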