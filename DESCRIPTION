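Package: latentcourse
Title: Latent Diffusion Modelling of Individual Brain Disease Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A scale-configurable pipeline for predicting individual-level
    disease progression in 3D brain images with a covariate-conditioned latent
    diffusion model. Includes a synthetic longitudinal phantom generator with
    diagnosis-dependent regional atrophy, a latent autoencoder, a conditional
    denoiser with deterministic DDIM sampling, an anatomy control network
    conditioned on a baseline scan, auxiliary disease-course volume forecasters,
    latent average stabilization with global and voxel-wise uncertainty, and
    image/volumetric evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
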