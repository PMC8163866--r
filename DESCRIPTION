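Package: mirscan
Title: Simulation and Reduced-Band Segmentation for Mid-Infrared Tissue Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Virtual-instrument simulation and analysis pipeline for
    discrete-wavenumber mid-infrared (MIR) flying-spot tissue scanning.
    Generates synthetic tissue phantoms (brain-like and liver-tumour-like
    label maps with per-class infrared absorbance profiles), simulates both
    a four-laser flying-spot MIR scanner and a full FT-IR hyperspectral
    imager from the same phantom, and implements the downstream workflow:
    background-referenced absorbance, threshold adjustment, locally adaptive
    total-variation denoising, normalization, k-means segmentation with
    background-cluster rejection, cross-modality structural-similarity
    comparison, and scan-time/data-load accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    yaml,
    mclust
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
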