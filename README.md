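# mirscan

Can three or four fixed mid-infrared wavenumbers replace a full hyperspectral
measurement for segmenting tissue? Discrete-band flying-spot MIR scanners
image a section with a handful of quantum-cascade/DFB laser lines — a
reference/target pair on the lipid C–H valence band (2790 / 2926 cm⁻¹) and a
reference/target pair on the protein amide-A N–H band (3350 / 3700 cm⁻¹) —
and promise orders-of-magnitude gains in scan time and data load over FT-IR
imaging, provided that k-means segmentation of the few-channel data still
finds the structures a pathologist cares about (hippocampus, white vs grey
matter, tumour margins).

`mirscan` makes that question testable without an instrument. It provides:

* **Tissue phantoms** — schematic coronal-brain and liver-with-tumour label
  maps on a physical grid, each class carrying an absorbance model
  `A(ν̃) = baseline + Σ_b a_b · exp(−(ν̃ − c_b)² / 2σ_b²)` (Gaussian bands over
  a scattering baseline), with an optional O–H water band scaled by a
  residual-water fraction.
* **Virtual instruments** — a four-laser flying-spot scanner (Beer–Lambert
  transflection forward model `I = I₀·R·10^(−A)·(1+ε)`, per-pixel
  oversampling, per-laser bare-slide background measurement) and an FT-IR
  imager (full spectrum per pixel, accumulation averaging).
* **The processing workflow** — background-referenced absorbance
  `A = −log₁₀(I/I_bg)`, co-registration, weak-signal threshold adjustment,
  locally adaptive total-variation denoising (primal–dual weighted-ROF with
  a noise-scaled weight), robust normalization; spectral smoothing, vector
  normalization and fingerprint/functional-group range restriction for the
  FT-IR cube.
* **Segmentation** — k-means (k-means++ seeding, restarts, Lloyd) on
  per-pixel spectral features with mask-majority background-cluster
  rejection, plus Dice / boundary-Hausdorff / adjusted-Rand concordance
  metrics.
* **Cross-modality comparison** — per-wavenumber SSIM and MSE between MIR
  laser images and matched FT-IR channels on a common grid, and
  scan-time / data-load accounting for the two modalities.

File formats are the imaging-spectroscopy staples: single-channel TIFF for
rasters, ENVI-style band-sequential cubes with a text header (bit-exact
round trip), CSV tables, YAML configs and manifests.

## Worked example

Segment the hippocampal band of a simulated 6 × 6 mm coronal section from
four wavenumbers at 5% relative intensity noise:

```r
library(mirscan)

phantom <- make_brain_phantom(c(6, 6), pixel_pitch_um = 20, seed = 1)
phantom
#> <tissue_phantom> 300 x 300 px @ 20 um (6.00 x 6.00 mm), 3 classes, water 0.00
#>   background        41836 px
#>   grey_matter       43513 px
#>   white_matter       3067 px
#>   hippocampus        1584 px

res <- run_mir_pipeline(phantom, k = 4,
                        scanner = scanner_config(noise_sd = 0.05), seed = 7)
res$map
#> <label_map> 300 x 300 px, k = 4, 1 rejected, WCSS 62.72

best_matching_cluster(res$map, phantom$labels == 3L)$dice
#> [1] 1
```

One cluster was rejected as bare-slide background; of the three kept
clusters, the one best matching the true hippocampal band overlaps it with
Dice 1.0 — the four-wavenumber scan segments the structure perfectly at this
noise level. The same pipeline run on a liver phantom with a 3 mm tumour
nodule (`make_liver_phantom`) recovers the nodule boundary at `k = 2` and,
with a graded infiltration margin, isolates the margin as the third cluster
at `k = 3`.

The command-line wrapper drives the same functions from a shell:

```sh
inst/exec/mirscan pipeline --config run.yaml --out results/
```

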