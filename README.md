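# HistoCLDM

Cluster-conditioned latent diffusion for **unlabeled** H&E histopathology
tiles, in pure R.

Histopathology archives are large and almost never annotated, which rules
out class-conditional generative models exactly where targeted synthetic
data would help most. HistoCLDM implements the alternative: manufacture the
conditioning signal from the data itself. Tiles are compressed into a
discrete latent space by a vector-quantized adversarial autoencoder
(VQ-GAN); the latent features are clustered without supervision by
mutual-information maximization; and the hard cluster IDs condition a
denoising diffusion model that runs in the latent space. The number of
clusters is selected by five internal validity indices, and generation
quality is scored per cluster count.

The package is aimed at computational-pathology and methods researchers who
want a fully inspectable, CPU-runnable implementation of this pipeline —
every network, gradient and metric is in plain R — together with a
synthetic H&E tile generator that makes the whole workflow testable without
any external dataset.

## The method in brief

- **Compression.** A VQ autoencoder with codebook $\{e_k\}$ trained with
  $L = L_{rec} + L_{cb} + \beta L_{commit} + \lambda_{perc} L_{perc} +
  \lambda_{adv} L_{adv}$ (β = 0.2; PatchGAN hinge adversary; LPIPS-style
  perceptual term; straight-through gradients through the quantizer).
- **Clustering.** A softmax head maximizes
  $\mathrm{MI} = H(\bar p) - \tfrac1n\sum_i H(p_i)$ (natural log, so
  $0 \le \mathrm{MI} \le \ln K$) plus a self-augmented-training consistency
  term: mean KL from the prediction on a tile to the prediction on its
  rotated/translated/rescaled version.
- **Cluster-count selection.** Direction-aware consensus over
  Calinski–Harabasz, C, Dunn, Hartigan ($\ln SSB/SSW$) and McClain–Rao
  indices; majority vote, ties to the smallest k.
- **Generation.** DDPM on standardized latents with a linear β schedule:
  $z_t = \sqrt{\bar\alpha_t}\,z_0 + \sqrt{1-\bar\alpha_t}\,\epsilon$, an
  ε-predicting conditional U-Net (timestep + cluster embeddings injected at
  every stage), ancestral sampling with the posterior variance
  $\tilde\beta_t$, and three training phases (initial / MSE-only finetuning
  with the clustering head frozen / consistency finetuning with nothing
  frozen).
- **Evaluation.** SSIM, MS-SSIM and a perceptual distance between generated
  tiles and their conditioning sources, plus *conditional fidelity*: the
  fraction of generated tiles whose re-encoded latent is assigned the
  cluster they were conditioned on.

## Worked example

```r
library(HistoCLDM)

# run the full desk-scale pipeline on synthetic tiles with 3 known classes
cfg <- deskConfig(kRange = 2:5, seed = 1, outDir = "run1")
man <- runPipeline(cfg, verbose = TRUE)
man$consensusK
#> [1] 3
unlist(man$reconstruction)
#>   mseTrained mseUntrained
#>   0.02040884   0.11902800
man$fidelityOverall
#> [1] 0.7083333
reportPipeline("run1")
```

What these numbers mean: from 48 unlabeled 32-px synthetic tiles drawn from
3 phenotypes, the validity-index consensus over the k = 2..5 sweep recovers
the true 3 classes; the trained autoencoder reconstructs held-out tiles
about 6× better than an untrained one; and 71% of diffusion samples are
re-assigned the cluster they were conditioned on (chance: 33%).

The selection procedures can also be used directly. On the bundled per-k
worked-example tables (a published analysis of this design with cluster
counts 10–16):

```r
consensusSelectK(referenceIndexTable())$k     # 14, winning all 5 indices
selectBestClusterSet(referenceMetricTable())$k  # 14, winning all 3 metrics
```

A thin command-line wrapper lives at `inst/cli/cldm.R`
(`make-fixtures`, `run-all`, `report`).

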