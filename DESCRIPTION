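Package: HistoCLDM
Title: Cluster-Conditioned Latent Diffusion for Unlabeled Histopathology Tiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for synthesizing unlabeled hematoxylin-and-eosin (H&E)
    histopathology tiles with a cluster-conditioned latent diffusion model.
    Tiles are compressed into a discrete latent space by a vector-quantized
    autoencoder trained with reconstruction, codebook, commitment, perceptual
    and patch-adversarial losses; latent features are clustered by
    mutual-information maximization with self-augmented-training consistency,
    and the hard cluster assignments condition a denoising diffusion
    probabilistic model run in the latent space. The cluster count is chosen
    by direction-aware consensus over five internal validity indices
    (Calinski-Harabasz, C, Dunn, Hartigan, McClain-Rao), and generated images
    are scored with SSIM, MS-SSIM and a learned perceptual (LPIPS-style)
    distance. Includes a synthetic H&E tile generator with known phenotype
    classes so the full pipeline is testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'HistoCLDM-package.R'
    'accessors.R'
    'clustering.R'
    'diffusion.R'
    'feature-extractor.R'
    'fixtures.R'
    'metrics-ssim.R'
    'nn-core.R'
    'pipeline.R'
    'reference-tables.R'
    'tiles-io.R'
    'validity-indices.R'
    'vqgan.R'
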