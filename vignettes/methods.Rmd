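---
title: "Cluster-conditioned latent diffusion for H&E tiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-conditioned latent diffusion for H&E tiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

HistoCLDM implements conditional image synthesis for *unlabeled*
hematoxylin-and-eosin (H&E) histopathology tiles. Because no annotations
exist, the conditioning signal is manufactured: tiles are compressed into a
learned discrete latent space, the latent features are clustered without
supervision, and the cluster ID of each tile becomes the class label that a
latent diffusion model is conditioned on. The number of clusters is not
assumed but chosen by internal validity indices, and the quality of
generation is assessed per cluster count with image-similarity metrics.

This vignette describes each model, its assumptions, the tunable parameters,
and the numerical choices the implementation makes.

# The autoencoder: vector-quantized, adversarially trained

`vqganModel()` builds an encoder/decoder pair around a discrete codebook.
The encoder maps a tile (rescaled from $[0,1]$ to $[-1,1]$ at the model
boundary) through stride-2 convolutions with residual blocks and SiLU
activations to an $h \times w \times d$ latent grid; with two downsampling
stages, 128-px tiles produce $32 \times 32$ grids and 32-px desk-scale tiles
produce $8 \times 8$ grids. Each latent vector is snapped to its nearest
codebook row (squared Euclidean distance, ties to the lowest index); the
decoder mirrors the encoder and ends in a tanh so outputs land in $[0,1]$
after inverse rescaling.

Training minimizes

$$L = L_{rec} + L_{cb} + \beta\, L_{commit}
      + \lambda_{perc}\, L_{perc} + \lambda_{adv}\, L_{adv}$$

* $L_{rec}$: pixel MSE between tile and reconstruction.
* $L_{cb}$: distance between the (stopped-gradient) encoder latent and its
  codebook vectors — this is the only term that updates the codebook
  (gradient-based, not exponential-moving-average, because the loss itself
  carries the codebook term).
* $L_{commit}$ with weight $\beta = 0.2$: the same distance with the
  stop-gradient on the codebook side, pulling the encoder toward its codes.
* $L_{perc}$: a feature-space distance (next section), weight
  $\lambda_{perc} = 1$.
* $L_{adv}$: a PatchGAN term — the discriminator scores every
  receptive-field patch separately and the losses are averaged over patches.
  We use the hinge form for the discriminator and $-\mathrm{mean}(\text{logits})$
  for the generator ($\lambda_{adv} = 0.5$), the standard stable pairing for
  this family, with a configurable warm-up during which the adversarial
  weight is zero.

The quantization bottleneck is bridged with the straight-through estimator:
the gradient of the decoder input with respect to the encoder output is the
identity. Unit tests pin this contract with finite differences.

At the quantization step, gradients flow as if quantization were the
identity; the codebook itself moves only through $L_{cb}$. Study-scale
defaults follow the source configuration (codebook $128 \times 16$, Adam,
learning rate $10^{-4}$, batch 16, 20 epochs).

**Desk scale.** Tests run a reduced configuration: 32-px tiles,
$8 \times 8 \times 8$ latents, a 32-row codebook, 16 epochs at learning rate
$10^{-3}$. Sixteen epochs (rather than a token handful) matter for a
specific reason: conditional fidelity is scored by *re-encoding* generated
tiles, so the encode–decode–encode cycle must approximately commute. At 6
desk epochs the cycle preserves cluster identity for only ~60% of
reconstructions; at 16 epochs for ~94%. The desk preset also leaves the
adversarial weight in warm-up for its whole (~100-step) run — at that step
count a discriminator only destabilizes; the adversarial path is exercised
by its own unit tests.

# The perceptual distance

`perceptualDistance()` (exposed as `lpipsMetric()` for evaluation) compares
deep feature maps: at every tapped layer, the channel vector at each spatial
position is normalized to unit length, squared differences are weighted by
non-negative per-channel weights, averaged spatially, and summed over
layers. The packaged extractor is a frozen convolutional stack with
fixed-seed random weights. Random features are a deliberate choice: they
preserve the structure of the metric (multi-scale, multi-channel, spatially
local) while keeping the package free of downloaded pretrained weights; any
extractor following the `FeatureExtractor` contract (including a pretrained
one) can be plugged in.

# Information-maximization clustering

`trainClustering()` fits a small head ($p \to 64 \to K$, SiLU then softmax)
by full-batch gradient ascent on the mutual information between inputs and
cluster assignments,

$$\mathrm{MI} = H\!\left(\bar p\right) - \frac1n \sum_i H(p_i),$$

where $\bar p$ is the mean assignment (marginal) and $H$ is the natural-log
entropy, so $0 \le \mathrm{MI} \le \ln K$. The marginal entropy rewards
balanced clusters, the conditional entropy rewards confident assignments. A
self-augmented-training (SAT) term adds the mean KL divergence from the
(fixed) prediction on a tile to the prediction on a transformed version of
it (90° rotations, integer translations, ±10% rescale — `augmentTile()`),
weight `muSat = 1` by default.

Two numerical choices make the ascent reliable and are worth recording:
features are standardized (the statistics are frozen inside the head so
later predictions see the same transform), and the output layer starts
near zero so the initial assignment is near-uniform. Without these, large
feature scales make the head confident in its random initial partition and
the confidence term locks in unbalanced local optima; with them the head
recovers well-separated synthetic structure essentially perfectly.

The clustering input is the mean-pooled embedded latent ($p = d$) by
default; `flatten` is available. Pooling keeps the head small and is
invariant to the spatial layout, which suits tiles whose class identity is a
global texture/color property.

# Choosing the cluster count

For each candidate $k$, `validityIndexReport()` computes five internal
indices on the clustered features: Calinski–Harabasz
($\frac{tr B_k}{tr W_k}\frac{n-k}{k-1}$), C index (sum of intra-cluster
pairwise distances located between its best and worst attainable values,
global-pool construction), Dunn (minimum single-linkage inter-cluster
distance over maximum cluster diameter), Hartigan ($\ln(SSB/SSW)$, exactly
this logarithmic form), and McClain–Rao (mean intra- over mean
inter-cluster distance). All use Euclidean distances, matching the
scatter-matrix forms of the first and fourth.

`consensusSelectK()` is direction-aware — CH, Dunn and Hartigan vote for
their maximizer, C and McClain–Rao for their minimizer — and selects the
majority winner, breaking ties toward the smallest k (the conservative
choice: fewer clusters claim less structure). The same majority machinery
drives `selectBestClusterSet()` over SSIM (max), MS-SSIM (max) and the
perceptual distance (min). The package bundles the per-k tables of a
published analysis of this design as worked examples
(`referenceIndexTable()`, `referenceMetricTable()`); both procedures select
the 14-cluster set on them, unanimously.

# The diffusion model

`linearSchedule()` defines $\beta_t$ linearly between its endpoints,
$\alpha_t = 1-\beta_t$, $\bar\alpha_t = \prod_{s\le t}\alpha_s$. The forward
marginal is the standard

$$z_t = \sqrt{\bar\alpha_t}\, z_0 + \sqrt{1-\bar\alpha_t}\,\epsilon .$$

(One printed source form omits the square root on the mean coefficient;
without it the chain does not preserve variance, so the implementation uses
the standard form.) The denoiser is a small U-Net over latent grids —
full-resolution stage, stride-2 stages to the bottleneck (two at study
scale: $32 \to 8$; one at desk scale: $8 \to 4$), nearest-neighbor
upsampling with additive skip connections. Timestep (fixed sinusoidal
embedding) and cluster ID (learned embedding table) are summed and injected
as per-channel biases at every stage — the minimal faithful conditioning
mechanism; no classifier-free guidance. Training minimizes the
noise-prediction MSE with $t$ uniform on $[1,T]$, unweighted. Sampling is
ancestral: $\mu_\theta = (z_t - \frac{\beta_t}{\sqrt{1-\bar\alpha_t}}
\hat\epsilon)/\sqrt{\alpha_t}$ with the fixed posterior variance
$\tilde\beta_t = \beta_t(1-\bar\alpha_{t-1})/(1-\bar\alpha_t)$ (the
$\epsilon$-objective pins down only the mean, so the variance is not
learned), and the final step returns the mean exactly.

Two latent-space conventions:

* **Standardization.** Before diffusion the latents are shifted/scaled by
  scalar statistics so their distribution is approximately unit-variance
  (the latent-diffusion "scale factor" convention); sampling inverts the
  transform. The forward process mixes toward $\mathcal N(0,1)$, so the data
  must live on that scale for the terminal distribution to match the prior.
* **Terminal signal-to-noise.** When the step count is reduced from
  $T=1000$ to a desk-scale $T$, the endpoints must grow accordingly or
  $\bar\alpha_T$ stays far from zero and sampling starts from a prior the
  forward chain never reaches — conditioning then cannot work at all. The
  desk preset uses the standard $1000/T$ endpoint scaling: $T = 50$ with
  $(\beta_1, \beta_T) = (0.002, 0.4)$, giving $\bar\alpha_T < 10^{-5}$, like
  the study-scale $(10^{-4}, 0.02)$ at $T = 1000$.
* Generated $z_0$ is quantized through the codebook before decoding, so the
  decoder always sees valid codebook embeddings.

**Three training phases** (`ldmPhases()`): initial training (Adadelta),
finetuning-1 (Adam, the clustering head frozen, objective reduced to the
noise-prediction MSE alone), finetuning-2 (Adadelta, nothing frozen, the
SAT/transformation-consistency term re-enabled — implemented as consistency
gradient steps on the clustering head with the conditioning labels refreshed
each epoch, the only transformation-consistency term in the system). The
study-scale recipe is 600/130/70 epochs at rates 0.003/1e-4/0.003. The desk
preset keeps the optimizer kinds and the freeze/consistency structure but
uses 60/15/15 epochs at rates 1.0/1e-3/1.0: Adadelta's classic operating
point is a unit rate, and a few hundred gradient steps at 0.003 simply do
not move the network. The autoencoder is frozen throughout all phases.

# The synthetic tile generator

Because the motivating tiles are not distributed, `generateTile()` renders
H&E-like tiles with controllable phenotypes: a near-white background; void
regions from thresholded smoothed noise (the threshold is the exact quantile
of the requested void fraction); an eosin-tinted band-pass stromal texture
whose floor guarantees tissue is distinguishable from background whenever
stromal intensity is positive; optional red-blood-cell recoloring; and
nuclei placed as a homogeneous spatial Poisson process with mean
`density * (1 - voidFraction) * size^2`, rendered as hematoxylin discs. The
14 presets in `phenotypeBank()` span dense/sparse cellularity, voids of
several sizes, RBC content, stroma-rich tissue, boundaries and near-empty
tiles — the qualitative categories a pathologist uses for tumor-section
tiles.

What the generator does *not* emulate: optical blur and chromatic noise of
real microscopy, stain variability between slides, spatial tissue
architecture (glands, vessels), or any specific real dataset's class
structure. Passing tests therefore demonstrate that the pipeline's
machinery — compression, clustering, k-selection, conditional generation,
evaluation — works end to end on data with known structure; they do not
certify performance on real slides.

# Desk-scale problem sizes and what the tests assert

The package's own test battery runs everything on one CPU. The sizes were
chosen once, as the smallest at which each property is meaningfully
testable: 3 phenotype classes, 48 training tiles of 32 px; VQ-GAN as above;
cluster sweep $k \in 2..5$ at 300 ascent iterations per k; $T = 50$;
sampling 8 tiles per cluster. Under these conditions (three seeds,
seed-median): held-out reconstruction MSE beats an untrained model by
several fold, the validity-index consensus recovers the true $k = 3$, and
generated tiles are re-assigned their conditioning cluster about 70% of the
time against a 33% chance level.

# Known limitations

* All networks are intentionally small and CPU-bound; the package
  demonstrates and tests the method, it is not tuned for photorealism.
* The clustering objective is non-convex; isolated seeds can land in local
  optima (the benchmark asserts the seed-median).
* The random-weight perceptual extractor ranks structural corruption well
  but is not a substitute for a pretrained perceptual metric when absolute
  perceptual scores matter.
* Whether clustering should consume pre- or post-quantization latents is
  genuinely open; the package uses post-quantization embeddings (the
  decoder-facing representation) and exposes the choice.
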