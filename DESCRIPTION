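Package: vfddpm
Title: Diffusion-Model Synthetic Augmentation for Vocal Fold Pathology Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully reproducible pipeline for studying whether
    synthetic laryngoscopy images generated by denoising diffusion
    probabilistic models (DDPMs) improve vocal fold structural pathology
    (VFSP) classification under severe class imbalance. Provides a
    procedural phantom laryngoscopy image generator with ground-truth lesion
    masks, a from-scratch DDPM (cosine noise schedule, noise-prediction
    denoiser, ancestral sampling), automated curation of synthetic images
    (sharpness and fold-structure plausibility filters), the three
    augmentation scenarios (synthetic-only, +10% originals, +50% originals)
    for binary and multi-class tasks, and an evaluation suite (confusion
    matrices, accuracy/precision/sensitivity/specificity/F1, Frechet
    distance between image feature distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
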