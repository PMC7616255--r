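Package: lesionsynth
Title: Progressive Adversarial Variational Auto-Encoders for 3D Brain
    Lesion Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage generative modelling of 3D brain lesions for data
    augmentation: a mask-synthesis variational auto-encoder conditioned on
    lesion size through a condition embedding block, and a mask-guided
    lesion-synthesis network using a spatially adaptive mask embedding
    block, both trained adversarially with a Wasserstein critic and
    gradient penalty. Includes a reverse-mode automatic differentiation
    engine with double-backpropagation (needed for the gradient penalty),
    NIfTI cube extraction and paste-back utilities, a synthetic lesion
    phantom generator, image-quality metrics (PSNR, SSIM, NMSE) and
    mask-agreement metrics (Dice, Jaccard, average surface distance, 95th
    percentile Hausdorff distance), and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
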