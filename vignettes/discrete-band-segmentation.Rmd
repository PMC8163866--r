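---
title: "Discrete-band MIR tissue segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete-band MIR tissue segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirscan)
```

## The question the package simulates

Full FT-IR hyperspectral imaging measures hundreds of wavenumbers per pixel
and is the reference method for label-free tissue characterization, but it
is slow and produces large data volumes. A flying-spot scanner built around
a few fixed mid-infrared laser lines measures only the bands that carry the
discriminative chemistry: lipid C–H valence vibrations peak at 2926 cm⁻¹,
the protein amide-A N–H band lies near 3350 cm⁻¹ (its exact position varies
over roughly 3200–3500 cm⁻¹ with protein composition), and 2790 / 3700 cm⁻¹
sit in low-absorbance wings of those bands, serving as scattering
references. If k-means clustering of these three-or-four values per pixel
segments the same structures as clustering of the full spectrum, the
discrete-band scanner wins on speed and data load by construction.

`mirscan` builds both instruments *in silico* around a common ground truth
(a tissue phantom), runs the identical downstream workflow on both, and
quantifies where the reduced-band measurement is equivalent and where it is
not.

## The phantom model

A phantom is a 2D integer label raster on a physical grid (label 0 = bare
mirrored slide) plus one spectral profile per tissue class. Profiles are
sums of Gaussian bands over a constant scattering baseline:

$$A(\tilde\nu) = A_0 + \sum_b a_b\, e^{-(\tilde\nu - c_b)^2 / 2\sigma_b^2}.$$

Gaussian shapes are an idealization chosen because only peak positions and
ranges of the real bands are established; they are smooth, analytic, and
place the reference wavenumbers in genuinely low-absorbance wings. The
default band table uses lipid C–H (2926, σ 60), amide A (3350, σ 90) and,
scaled by the `water_fraction` parameter, a broad O–H band (3400, σ 180)
that superposes both target bands — the reason sections are dried before
measurement; `water_fraction = 0` is the dried condition, and absorbance at
3350 cm⁻¹ increases strictly with it.

Class amplitudes are free parameters (absolute per-class absorbances are
not established quantities), fixed once so that at 2926 cm⁻¹ white matter
(0.80) > hippocampal band (0.45) > grey matter (0.30) — the ordering the
lipid chemistry dictates — and so that the hippocampal class has a distinct
lipid-to-amide ratio. The liver pair differs mainly in the C–H band
(healthy 0.40 vs tumour 0.75), reflecting the elevated long-chain C–H
content of the malignancy; baselines are 0.04–0.05.

Geometry is schematic topology, not anatomy: an elliptical grey-matter
section with an arched white-matter band and a curved hippocampal band
nested inside it; an elliptical liver section with a 3 mm nodule toward the
left lobe whose boundary is perturbed by seeded low-frequency radial
harmonics (`margin_irregularity`, default 0.3 — visible infiltration-like
irregularity that preserves the equivalent-disc area to well under 5%). The
default liver boundary is sharp (`margin_width_mm = 0`); the graded-margin
experiments add an explicit transition class whose spectrum is the mean of
its neighbours.

## The forward model

Both instruments see the phantom through the same transflection
Beer–Lambert law relative to the bare slide,

$$I = I_0\, R_\text{slide}\, 10^{-A(\tilde\nu)} (1 + \varepsilon),
\qquad \varepsilon \sim \mathcal N(0, \sigma_\text{rel}),$$

with the double pass through the section folded into the effective `A`
(only the sample/background ratio is observable). Noise is multiplicative
relative-intensity noise per raw sample — a deliberate simplification (no
detector model is established) that keeps absorbance noise approximately
additive at small σ. The MIR scanner draws `oversampling` samples per pixel
and averages them (noise ∝ 1/√f, verified by Monte-Carlo), and measures a
bare-slide background raster per laser; the FT-IR imager averages
`accumulations` intensity draws per pixel and channel. With σ = 0,
`−log₁₀(I/I_bg)` recovers the phantom absorbance exactly (tested at 1e−9).

Line offsets (0.5 cm at each line end) and mirror velocity enter the timing
accounting only. The real instrument's line duty cycle (flyback,
bidirectionality) is unspecified, so the implied stage speed is derived
from configuration and wall-clock scan times are treated strictly as
supplied measurements, never derived — which is why the scan-time factor in
the throughput report is computed from user-provided times.

## Pre-processing

The MIR chain runs in a fixed, logged order: absorbance → align →
threshold adjustment → TV denoising → normalization.

* **Align.** Simulated lasers share one grid (perfect co-registration), so
  shift estimation is opt-in. When enabled, integer shifts are estimated by
  circular cross-correlation against the first image; an estimated shift
  above 10% of the extent signals alignment failure and leaves the inputs
  untouched. On a noise-dominated channel the correlation peak is random,
  which is exactly when the 10% rule fires — the reason estimation is not
  run by default on data known to be co-registered.
* **Threshold adjustment** amplifies weak signals with the continuous
  piecewise-linear map `x ↦ min(gain·x, T)` below the threshold `T` (a low
  percentile by default), identity above; `gain = 1` is the identity.
* **TV denoising** minimizes the weighted Rudin–Osher–Fatemi energy
  `Σ w(x)|∇u| + ½Σ(u−f)²` with a primal–dual (Chambolle–Pock) scheme
  (step 1/√8, 60 iterations — comfortably converged for these weights).
  Two choices matter. First, the weight is *noise-scaled*: `w = strength ·
  σ̂`, with σ̂ the robust median-absolute-difference noise estimate, so that
  channels with a tenth of the dynamic range (the reference lasers) receive
  proportionate smoothing and a noise-free image passes through bit-exact.
  Second, the weight is *locally adaptive*: scaled down where the windowed
  variance of the gradient magnitude is high (edges), up in flat windows.
  The default `strength = 4` noise-sd units halves flat-region noise many
  times over while moving a step edge's 50% crossing by at most one pixel
  (both are contract tests). Without noise scaling, the min–max
  normalization that follows would amplify residual reference-channel noise
  to order one, and k-means would split large uniform classes along that
  noise instead of isolating small structures — the single most important
  numerical interaction in the pipeline.
* **Normalization** maps the 1st/99th percentiles to [0, 1] with clipping;
  it is affine-invariant and errors on degenerate (constant) images.

The FT-IR chain is spectral: moving-average smoothing along the wavenumber
axis (window 5, truncated at the ends), per-pixel scaling to unit Euclidean
norm (the standard vector normalization before clustering; optional, and
disabled when channels are compared as images), then restriction to the
fingerprint (750–1500 cm⁻¹) and functional-group (2500–4000 cm⁻¹) regions.

## Segmentation and background rejection

Features are the per-pixel channel vectors (3–4 for MIR, >100 for FT-IR).
Clustering is Lloyd k-means from k-means++ seeds, best of 5 restarts by
within-cluster sum of squares, deterministic given a seed, clusters
relabelled by descending size. k is a user parameter (4 for the brain
experiments, 2 and 3 for the liver ones); no model selection is attempted.
Because k-means reproducibility is a genuine caveat of the method,
`segmentation_stability()` reports the adjusted Rand index across seeds
rather than assuming stability.

Background handling replaces a data-dependent "first clusters are
background" observation with an explicit rule: after clustering, any
cluster whose pixels are mostly (majority > 0.5) outside a tissue mask is
rejected and relabelled −1. In simulation the mask is the phantom truth;
for measured data an Otsu threshold on mean absorbance is provided.

Two masking decisions were genuinely open and are worth recording:

* **Liver at k = 2.** With bare slide in frame, the optimal 2-way partition
  of a nearly-binary tissue is slide-vs-tissue, not healthy-vs-tumour
  (measured: tumour Dice 0.46 unmasked vs 1.0 masked). The liver
  experiments therefore cluster within the tissue mask, mirroring
  measurements in which the section fills the cropped field. The default
  remains cluster-first-reject-second; masking is an explicit option.
* **Cross-modality agreement at equal k.** The concordance experiment uses
  k = 3 within tissue on both arms — the phantom's tissue class count. At
  k = 4 the spare centroid splits grey matter along modality-specific
  noise, so the score measures k-means instability rather than modality
  agreement (ARI drops from 1.0 to ≈0.26 for that reason alone).

Unmasked FT-IR clustering spends centroids on the slide: unit-normalized
noise spectra are mutually distant random directions. This is left as
honest behaviour — it is the computational analogue of background clusters
dominating low k in real measurements — and the rejection rule handles it.

## Comparison metrics

`channel_similarity` extracts the nearest FT-IR channel per laser
wavenumber (erroring when the gap exceeds the spectral spacing), resamples
it to the MIR grid bilinearly (exact for affine fields, linear
extrapolation at the half-pixel border), applies the image-domain denoiser
to both sides (identity on noise-free inputs — the workflow denoises the
measurement images of both modalities before comparison), normalizes both
identically, and reports SSIM and MSE per channel plus the mean. SSIM is
the standard windowed luminance·contrast·structure product (uniform 7 × 7
window, C₁ = (0.01 L)², C₂ = (0.03 L)², border of half a window excluded).
Both statistics are reported separately; an intensity-only difference
lowers SSIM through the luminance/contrast terms while the structure term
stays at 1, which is the diagnostic the comparison is designed to expose.

`label_concordance` matches kept clusters one-to-one by exhaustive
assignment on Dice overlap (≤8 clusters) and reports per-class Dice plus
the adjusted Rand index over jointly kept pixels. `throughput_report`
counts pixels from the grid arithmetic, channels from the laser table (MIR)
or the restricted preprocessed axis (FT-IR — the channel count actually
clustered, printed alongside the ratio), and forms data and time ratios
from supplied scan times.

## Problem sizes and numerical choices

The test-suite and acceptance experiments use phantoms between 3 × 3 and
10 × 10 mm at 20 µm pitch (up to the full 500 × 500 = 250k-pixel field of a
1 cm² scan) with relative noise 0.05, and an FT-IR axis at 2 cm⁻¹ spacing
over 2700–4000 cm⁻¹ for channel-exact laser matching; these sizes keep a
full run around a minute while exercising every stage at realistic pixel
counts. Other conventions: 0-based, row-major pixel coordinates with
half-open ROIs; absorbance floored at 0 after background referencing (noise
can push I > I_bg); all-zero spectra are left at zero by vector
normalization; ENVI cubes are double-precision band-sequential with the
wavenumber axis in the header, round-tripping bit-exactly.

## What passing these simulations does and does not show

The phantom reproduces the *statistical* structure the workflow relies on —
distinct class chemistry in the functional-group region, low-absorbance
reference wings, background/tissue contrast, Beer–Lambert noise — but not
optical scattering structure (no Mie/EMSC effects), no spatial
heterogeneity within a class, no water-vapour or baseline drift, no
misregistration between modalities unless injected, and schematic geometry
only. Perfect Dice scores at 5% noise therefore demonstrate that the
pipeline is correct and that the discrete-band information is sufficient
*under the stated model*; they do not predict segmentation quality on real
sections, where within-class variability and scattering dominate. The
throughput factors are arithmetic consequences of supplied scan times and
channel counts, not measurements.
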