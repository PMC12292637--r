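## DDPM in the autoencoder latent space, conditioned on cluster IDs.
##
## Forward process: z_t = sqrt(abar_t) z_0 + sqrt(1 - abar_t) eps (the
## standard closed-form marginal of the Gaussian chain). Reverse process: a
## U-Net-shaped denoiser predicts the injected noise eps from (z_t, t, c);
## the posterior mean is mu = (z_t - beta_t/sqrt(1-abar_t) * epsHat) /
## sqrt(alpha_t) and the variance is fixed to the posterior value
## betaTilde_t = beta_t (1 - abar_{t-1}) / (1 - abar_t). The condition c is
## a learned class embedding added to the sinusoidal timestep embedding and
## injected at every block.

#' Linear noise schedule
#'
#' Betas linearly spaced from `betaStart` to `betaEnd` inclusive;
#' `alphas = 1 - betas`, `alphaBars = cumprod(alphas)`. Study-scale default:
#' T = 1000 with the community-standard endpoints (1e-4, 0.02), under which
#' `alphaBars[T] < 0.01` (near-total noising).
#'
#' @param nSteps number of timesteps T (>= 1).
#' @param betaStart,betaEnd schedule endpoints, `0 < betaStart <= betaEnd < 1`.
#' @return a [NoiseSchedule-class].
#' @export
#' @examples
#' linearSchedule(2, 0.1, 0.3)  # betas 0.1, 0.3; alphaBars 0.9, 0.63
linearSchedule <- function(nSteps = 1000L, betaStart = 1e-4, betaEnd = 0.02) {
  if (nSteps < 1L)
    stop("invalid argument: nSteps must be >= 1")
  if (betaStart <= 0 || betaEnd >= 1 || betaStart > betaEnd)
    stop("invalid argument: need 0 < betaStart <= betaEnd < 1")
  betas <- seq(betaStart, betaEnd, length.out = nSteps)
  alphas <- 1 - betas
  new("NoiseSchedule", nSteps = as.integer(nSteps), betas = betas,
      alphas = alphas, alphaBars = cumprod(alphas))
}

#' Sample the forward (noising) marginal
#'
#' Returns `sqrt(alphaBars[t]) * z0 + sqrt(1 - alphaBars[t]) * eps`.
#'
#' @param z0 clean latent array.
#' @param t timestep in [1, T].
#' @param eps noise array, same shape as `z0`.
#' @param schedule a [NoiseSchedule-class].
#' @return the noised latent, same shape as `z0`.
#' @export
qSample <- function(z0, t, eps, schedule) {
  if (t < 1L || t > schedule@nSteps)
    stop("invalid argument: t must lie in [1, ", schedule@nSteps, "]")
  ab <- schedule@alphaBars[t]
  sqrt(ab) * z0 + sqrt(1 - ab) * eps
}

#' Noise-prediction loss
#'
#' Mean squared error between the injected and the predicted noise.
#'
#' @param eps,epsHat equal-shape numeric arrays.
#' @return a non-negative scalar.
#' @export
denoiseLoss <- function(eps, epsHat) {
  if (!identical(dim(eps), dim(epsHat)) && length(eps) != length(epsHat))
    stop("invalid argument: shapes disagree")
  if (anyNA(eps) || anyNA(epsHat)) stop("numeric error: NaN input")
  mean((eps - epsHat)^2)
}

## ---- the conditional denoiser ----

sinusoidalEmbedding <- function(t, embDim) {
  half <- embDim %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1L) / half)
  ang <- outer(freqs, t)            # [half, N]
  rbind(sin(ang), cos(ang))         # [embDim, N]
}

#' Construct the conditional latent denoiser
#'
#' A small U-Net over latent grids: a full-resolution stage, `nDown`
#' stride-2 downsamplings to the bottleneck, nearest-neighbor upsampling
#' with additive skip connections back to full resolution, SiLU activations
#' throughout. The timestep enters through a fixed sinusoidal embedding,
#' the cluster ID through a learned embedding table; their sum is projected
#' and added channelwise at each stage. At study scale (32 x 32 latents)
#' two downsamplings give the 8 x 8 bottleneck; desk-scale 8 x 8 latents
#' use one.
#'
#' @param latentDim channels d of the latent grid.
#' @param K number of condition classes.
#' @param channels base channel width.
#' @param embDim timestep/class embedding dimension (even).
#' @param nDown number of downsampling stages (>= 1).
#' @param seed RNG seed for initialization.
#' @return a list of class `"DenoiserNet"`.
#' @export
makeDenoiser <- function(latentDim, K, channels = 32L, embDim = 32L,
                         nDown = 1L, seed = 1L) {
  C <- as.integer(channels)
  C2 <- 2L * C
  withr::with_seed(as.integer(seed), {
    down <- lapply(seq_len(nDown), function(i) {
      cin <- if (i == 1L) C else C2
      list(conv = makeConv(4L, cin, C2, stride = 2L, pad = 1L),
           proj = list(W = matrix(stats::rnorm(embDim * C2,
                                               sd = sqrt(1 / embDim)),
                                  embDim, C2), b = numeric(C2)),
           res = makeResBlock(C2))
    })
    up <- lapply(seq_len(nDown), function(i) {
      cout <- if (i == nDown) C else C2
      list(conv = makeConv(3L, C2, cout),
           res = makeResBlock(cout))
    })
    structure(list(
      classEmb = matrix(stats::rnorm(K * embDim, sd = 0.1), K, embDim),
      convIn = makeConv(3L, latentDim, C),
      projIn = list(W = matrix(stats::rnorm(embDim * C, sd = sqrt(1 / embDim)),
                               embDim, C), b = numeric(C)),
      resIn = makeResBlock(C),
      down = down, up = up,
      convOut = makeConv(3L, C, latentDim, scale = 0.1),
      config = list(latentDim = as.integer(latentDim), K = as.integer(K),
                    channels = C, embDim = as.integer(embDim),
                    nDown = as.integer(nDown), seed = as.integer(seed))
    ), class = "DenoiserNet")
  })
}

#' @export
print.DenoiserNet <- function(x, ...) {
  cf <- x$config
  cat(sprintf(
    "DenoiserNet: d = %d, %d classes, %d base channels, %d down stage(s)\n",
    cf$latentDim, cf$K, cf$channels, cf$nDown))
  invisible(x)
}

## add per-sample channel bias: h[, , ch, n] + B[n, ch]
addChannelBias <- function(h, B) {
  d <- dim(h)
  h + aperm(array(t(B), c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2))
}

## spatial sum of dout per (sample, channel): returns [N, C]
channelBiasGrad <- function(dout) {
  d <- dim(dout)
  t(apply(dout, 4L, function(a) apply(array(a, d[1:3]), 3L, sum)))
}

## Forward pass of the denoiser on a batch. x [h,w,d,N]; t, cond length N
## (cond 0-based). Returns eps-hat and caches for the backward pass.
denoiserForward <- function(net, x, t, cond, keepCaches = FALSE) {
  cf <- net$config
  N <- dim(x)[4]
  temb <- sinusoidalEmbedding(t, cf$embDim)        # [E, N]
  eAll <- temb + t(net$classEmb[cond + 1L, , drop = FALSE])
  cache <- list(e = eAll, cond = cond)
  bIn <- t(eAll) %*% net$projIn$W + rep(net$projIn$b, each = N)
  f1 <- convForward(x, net$convIn)
  a1 <- siluForward(addChannelBias(f1$out, bIn))
  r1 <- resForward(a1$out, net$resIn)
  cache$f1 <- f1$cache; cache$a1 <- a1$cache; cache$r1 <- r1$cache
  h <- r1$out
  skips <- list(h)
  cache$down <- vector("list", cf$nDown)
  for (i in seq_len(cf$nDown)) {
    st <- net$down[[i]]
    fc <- convForward(h, st$conv)
    bi <- t(eAll) %*% st$proj$W + rep(st$proj$b, each = N)
    ac <- siluForward(addChannelBias(fc$out, bi))
    rc <- resForward(ac$out, st$res)
    cache$down[[i]] <- list(fc = fc$cache, ac = ac$cache, rc = rc$cache)
    h <- rc$out
    if (i < cf$nDown) skips <- c(skips, list(h))
  }
  cache$up <- vector("list", cf$nDown)
  for (i in seq_len(cf$nDown)) {
    st <- net$up[[i]]
    uu <- upsampleForward(h)
    uc <- convForward(uu$out, st$conv)
    ua <- siluForward(uc$out)
    skip <- skips[[length(skips) - i + 1L]]
    summed <- ua$out + skip
    ur <- resForward(summed, st$res)
    cache$up[[i]] <- list(uu = uu$cache, uc = uc$cache, ua = ua$cache,
                          ur = ur$cache)
    h <- ur$out
  }
  fo <- convForward(h, net$convOut)
  cache$fo <- fo$cache
  list(out = fo$out, cache = if (keepCaches) cache else NULL)
}

## Backward pass; returns gradients for every trainable component.
denoiserBackward <- function(net, dout, cache) {
  cf <- net$config
  N <- ncol(cache$e)
  gClassEmb <- matrix(0, nrow(net$classEmb), ncol(net$classEmb))
  dE <- matrix(0, cf$embDim, N)
  bo <- convBackward(dout, net$convOut, cache$fo)
  gConvOut <- bo$grads
  dh <- bo$dx
  gUp <- vector("list", cf$nDown)
  dSkips <- vector("list", cf$nDown)   # gradient flowing into each skip
  for (i in rev(seq_len(cf$nDown))) {
    st <- net$up[[i]]
    cc <- cache$up[[i]]
    br <- resBackward(dh, st$res, cc$ur)
    dSkips[[i]] <- br$dx              # skip branch shares this gradient
    da <- siluBackward(br$dx, cc$ua)
    bc <- convBackward(da, st$conv, cc$uc)
    dh <- upsampleBackward(bc$dx, cc$uu)
    gUp[[i]] <- list(conv = bc$grads, res = br$grads)
  }
  gDown <- vector("list", cf$nDown)
  for (i in rev(seq_len(cf$nDown))) {
    st <- net$down[[i]]
    cc <- cache$down[[i]]
    ## skip out of stage i's output feeds up-stage nDown - i + 1 ... only
    ## intermediate downs contribute; the innermost output went straight up
    if (i < cf$nDown)
      dh <- dh + dSkips[[cf$nDown - i]]
    br <- resBackward(dh, st$res, cc$rc)
    da <- siluBackward(br$dx, cc$ac)
    dB <- channelBiasGrad(da)
    gProj <- list(W = cache$e %*% dB, b = colSums(dB))
    dE <- dE + st$proj$W %*% t(dB)
    bc <- convBackward(da, st$conv, cc$fc)
    dh <- bc$dx
    gDown[[i]] <- list(conv = bc$grads, proj = gProj, res = br$grads)
  }
  dh <- dh + dSkips[[cf$nDown]]        # skip from the input stage
  br <- resBackward(dh, net$resIn, cache$r1)
  da <- siluBackward(br$dx, cache$a1)
  dB <- channelBiasGrad(da)
  gProjIn <- list(W = cache$e %*% dB, b = colSums(dB))
  dE <- dE + net$projIn$W %*% t(dB)
  bc <- convBackward(da, net$convIn, cache$f1)
  for (n in seq_len(N))
    gClassEmb[cache$cond[n] + 1L, ] <-
      gClassEmb[cache$cond[n] + 1L, ] + dE[, n]
  list(classEmb = gClassEmb, convIn = bc$grads, projIn = gProjIn,
       resIn = br$grads, down = gDown, up = gUp, convOut = gConvOut)
}

#' Apply the denoiser to one latent
#'
#' @param net a [makeDenoiser()] network.
#' @param z `h x w x d` latent array.
#' @param t timestep.
#' @param conditionId 0-based cluster ID.
#' @return the predicted noise, same shape as `z`.
#' @export
predictNoise <- function(net, z, t, conditionId) {
  d <- dim(z)
  out <- denoiserForward(net, array(z, c(d, 1L)), t, conditionId)$out
  out[, , , 1L, drop = TRUE]
}

#' One ancestral sampling step of the reverse process
#'
#' Computes the posterior mean from the predicted noise and adds posterior
#' noise for t > 1; the final step (t = 1) returns the mean exactly.
#'
#' @param zT current latent `h x w x d` at timestep `t`.
#' @param t timestep in [1, T].
#' @param conditionId 0-based cluster ID.
#' @param net the denoiser.
#' @param schedule a [NoiseSchedule-class].
#' @param noise optional pre-drawn standard-normal array (for testing);
#'   drawn internally otherwise.
#' @return the latent at timestep t - 1.
#' @export
pSampleStep <- function(zT, t, conditionId, net, schedule, noise = NULL) {
  if (t < 1L || t > schedule@nSteps)
    stop("invalid argument: t must lie in [1, ", schedule@nSteps, "]")
  epsHat <- if (is.function(net)) net(zT, t, conditionId) else
    predictNoise(net, zT, t, conditionId)
  bt <- schedule@betas[t]
  at <- schedule@alphas[t]
  ab <- schedule@alphaBars[t]
  mu <- (zT - bt / sqrt(1 - ab) * epsHat) / sqrt(at)
  if (t == 1L) return(mu)
  abPrev <- schedule@alphaBars[t - 1L]
  sigma2 <- bt * (1 - abPrev) / (1 - ab)
  if (is.null(noise)) noise <- array(stats::rnorm(length(zT)), dim(zT))
  mu + sqrt(sigma2) * noise
}

#' Sample latents for one condition
#'
#' Draws `z_T` from a standard normal and applies [pSampleStep()] for
#' t = T..1.
#'
#' @param n number of samples.
#' @param conditionId 0-based cluster ID.
#' @param net the trained denoiser (or a function `(z, t, c) -> eps`).
#' @param schedule a [NoiseSchedule-class].
#' @param latentShape `c(h, w, d)`.
#' @param seed RNG seed.
#' @return a list of `h x w x d` latent arrays.
#' @export
sampleLatents <- function(n, conditionId, net, schedule, latentShape,
                          seed = 1L) {
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      z <- array(stats::rnorm(prod(latentShape)), latentShape)
      for (t in rev(seq_len(schedule@nSteps))) {
        z <- pSampleStep(z, t, conditionId, net, schedule)
        if (anyNA(z) || any(!is.finite(z)))
          stop("non-finite latent during sampling at timestep ", t)
      }
      z
    })
  })
}

#' Generate tiles for a condition through the frozen decoder
#'
#' Samples latents, undoes the training-time latent standardization,
#' quantizes through the codebook (so decoded inputs are valid codebook
#' embeddings) and decodes.
#'
#' @param ldm a trained latent diffusion bundle from [trainLDM()].
#' @param vq the frozen [vqganModel()].
#' @param n number of tiles.
#' @param conditionId 0-based cluster ID.
#' @param seed RNG seed.
#' @return a [TileSet-class].
#' @export
sampleTiles <- function(ldm, vq, n, conditionId, seed = 1L) {
  zs <- sampleLatents(n, conditionId, ldm$net, ldm$schedule,
                      ldm$latentShape, seed = seed)
  tl <- lapply(zs, function(z) {
    z <- z * ldm$scale + ldm$shift
    decodeLatent(vq, quantizeLatent(z, vq$codebook))
  })
  TileSet(tl, ids = sprintf("gen_c%02d_%04d", conditionId,
                            seq_len(n) - 1L),
          labels = rep(as.integer(conditionId), n), split = "test")
}

## ---- training ----

#' Default three-phase training protocol
#'
#' Initial training (Adadelta, lr 0.003), finetuning-1 (Adam, lr 1e-4, the
#' clustering head frozen, pure noise-prediction MSE), finetuning-2
#' (Adadelta, lr 0.003, the SAT/transformation consistency term re-enabled,
#' nothing frozen). Study-scale epochs are 600/130/70; pass reduced epochs
#' for desk-scale runs.
#'
#' @param epochs integer vector of three epoch counts.
#' @param lrs numeric vector of three phase learning rates. The defaults
#'   are the study-scale values; desk-scale runs use larger rates (classic
#'   Adadelta operates at a unit rate) since only a few hundred gradient
#'   steps are taken.
#' @return a list of three phase specifications.
#' @export
ldmPhases <- function(epochs = c(600L, 130L, 70L),
                      lrs = c(0.003, 1e-4, 0.003)) {
  list(
    list(name = "initial", optimizer = "adadelta", lr = lrs[1],
         epochs = epochs[1], freezeClusterHead = FALSE, useSat = FALSE),
    list(name = "finetune1", optimizer = "adam", lr = lrs[2],
         epochs = epochs[2], freezeClusterHead = TRUE, useSat = FALSE),
    list(name = "finetune2", optimizer = "adadelta", lr = lrs[3],
         epochs = epochs[3], freezeClusterHead = FALSE, useSat = TRUE)
  )
}

#' Train the conditional latent diffusion model
#'
#' Per step: timesteps are drawn uniformly in [1, T], noise is injected via
#' [qSample()], and the denoiser minimizes the noise-prediction MSE. The
#' latents are standardized (scalar shift/scale) before diffusion so the
#' terminal distribution matches the standard-normal prior; sampling undoes
#' the standardization. During phases with `useSat = TRUE` and an attached
#' clustering head, the head additionally takes consistency-gradient steps
#' on (features, augmented features) pairs and the conditioning labels are
#' refreshed from the updated head each epoch; phases with
#' `freezeClusterHead = TRUE` leave every head parameter untouched. The
#' autoencoder is frozen throughout (it never enters this objective).
#'
#' @param latents list of `h x w x d` clean latent arrays.
#' @param conditions integer vector of 0-based cluster IDs, aligned with
#'   `latents`.
#' @param K number of condition classes.
#' @param phases list of phase specs (see [ldmPhases()]).
#' @param schedule a [NoiseSchedule-class].
#' @param net optionally an existing [makeDenoiser()] to continue training.
#' @param batchSize,channels,embDim,nDown training/architecture settings.
#' @param head,features,augmented optional clustering head and its paired
#'   feature matrices, enabling the SAT phase and label refresh.
#' @param muSat weight of the SAT term applied to the head.
#' @param seed RNG seed.
#' @param verbose print per-phase progress.
#' @return a list of class `"LatentDiffusion"`: `net`, `schedule`,
#'   `latentShape`, `shift`, `scale`, `head` (possibly updated),
#'   `conditions` (possibly refreshed), `losses` (data.frame: phase, epoch,
#'   mse, sat_loss).
#' @export
trainLDM <- function(latents, conditions, K, phases = ldmPhases(c(4L, 2L, 2L)),
                     schedule = linearSchedule(50L), net = NULL,
                     batchSize = 16L, channels = 32L, embDim = 32L,
                     nDown = 1L, head = NULL, features = NULL,
                     augmented = NULL, muSat = 1.0, seed = 1L,
                     verbose = FALSE) {
  n <- length(latents)
  if (n == 0L || length(conditions) != n)
    stop("invalid argument: latents and conditions must align")
  if (any(conditions < 0L) || any(conditions >= K))
    stop("invalid argument: conditions must lie in [0, K)")
  if (!length(phases)) stop("invalid argument: phases must be non-empty")
  latentShape <- dim(latents[[1]])
  allVals <- unlist(latents)
  shift <- mean(allVals)
  scale <- stats::sd(allVals)
  if (!is.finite(scale) || scale <= 0) scale <- 1
  zs <- lapply(latents, function(z) (z - shift) / scale)
  if (is.null(net))
    net <- makeDenoiser(latentShape[3], K, channels = channels,
                        embDim = embDim, nDown = nDown, seed = seed)
  conditions <- as.integer(conditions)
  lossRows <- list()
  set.seed(as.integer(seed))
  for (ph in phases) {
    opt <- makeOptimizer(ph$optimizer, net, ph$lr)
    headOpt <- NULL
    if (isTRUE(ph$useSat) && !isTRUE(ph$freezeClusterHead) &&
        !is.null(head) && !is.null(features) && !is.null(augmented))
      headOpt <- makeOptimizer("adam", head[c("W1", "b1", "W2", "b2")], 1e-3)
    for (ep in seq_len(ph$epochs)) {
      ord <- sample.int(n)
      mseAcc <- 0; nb <- 0L
      for (b in seq(1L, n, by = batchSize)) {
        take <- ord[b:min(b + batchSize - 1L, n)]
        N <- length(take)
        x0 <- stackTiles(zs[take])
        tt <- sample.int(schedule@nSteps, N, replace = TRUE)
        eps <- array(stats::rnorm(length(x0)), dim(x0))
        xt <- x0
        for (j in seq_len(N))
          xt[, , , j] <- qSample(x0[, , , j], tt[j], eps[, , , j], schedule)
        fw <- denoiserForward(net, xt, tt, conditions[take],
                              keepCaches = TRUE)
        mse <- mean((eps - fw$out)^2)
        if (!is.finite(mse))
          stop("non-finite diffusion loss in phase ", ph$name)
        g <- denoiserBackward(net, 2 * (fw$out - eps) / length(eps),
                              fw$cache)
        net2 <- opt(net, g)
        net2$config <- net$config
        net <- net2
        mseAcc <- mseAcc + mse; nb <- nb + 1L
      }
      satVal <- 0
      if (!is.null(headOpt)) {
        ## transformation-consistency step on the clustering head
        fwO <- headForward(head, as.matrix(features))
        fwA <- headForward(head, as.matrix(augmented))
        satVal <- satLoss(fwO$P, fwA$P)
        dZ2A <- muSat * (fwA$P - fwO$P) / nrow(fwO$P)
        gH <- headBackward(head, fwA, dZ2A)
        head[c("W1", "b1", "W2", "b2")] <-
          headOpt(head[c("W1", "b1", "W2", "b2")], gH)
        conditions <- hardLabels(softAssign(head, as.matrix(features)))
      }
      lossRows[[length(lossRows) + 1L]] <-
        data.frame(phase = ph$name, epoch = ep, mse = mseAcc / nb,
                   sat_loss = satVal)
      if (verbose)
        message(sprintf("[%s] epoch %d: mse %.4f", ph$name, ep, mseAcc / nb))
    }
  }
  structure(list(net = net, schedule = schedule, latentShape = latentShape,
                 shift = shift, scale = scale, head = head,
                 conditions = conditions,
                 losses = do.call(rbind, lossRows)),
            class = "LatentDiffusion")
}

#' @export
print.LatentDiffusion <- function(x, ...) {
  cat(sprintf(
    "LatentDiffusion: %s latents, T = %d, %d condition class(es)\n",
    paste(x$latentShape, collapse = "x"), x$schedule@nSteps,
    x$net$config$K))
  invisible(x)
}

#' Conditional fidelity of generated tiles
#'
#' Re-encodes each generated tile through the frozen autoencoder, assigns a
#' cluster with the frozen clustering head, and reports the fraction of
#' tiles assigned the cluster they were conditioned on, per cluster and
#' overall.
#'
#' @param generated a [TileSet-class] of generated tiles.
#' @param intended integer vector of 0-based intended cluster IDs, aligned
#'   with `generated`.
#' @param vq the frozen [vqganModel()].
#' @param head the frozen [clusterHead()].
#' @param featureMode pooling mode passed to [latentFeatures()].
#' @return a list with `table` (data.frame: cluster, n, correct, accuracy)
#'   and `overall` (fraction correct).
#' @export
conditionalFidelity <- function(generated, intended, vq, head,
                                featureMode = "mean-pool") {
  if (length(generated) != length(intended))
    stop("invalid argument: generated tiles and intended IDs must align")
  feats <- t(vapply(tiles(generated), function(tl) {
    q <- quantizeLatent(encodeTile(vq, tl), vq$codebook)
    latentFeatures(q, featureMode)
  }, numeric(if (featureMode == "mean-pool") vq$config$latentDim
             else prod(dim(encodeTile(vq, tiles(generated)[[1]]))))))
  pred <- hardLabels(softAssign(head, feats))
  intended <- as.integer(intended)
  ids <- sort(unique(intended))
  tab <- do.call(rbind, lapply(ids, function(cl) {
    sel <- intended == cl
    data.frame(cluster = cl, n = sum(sel),
               correct = sum(pred[sel] == cl),
               accuracy = mean(pred[sel] == cl))
  }))
  list(table = tab, overall = mean(pred == intended))
}
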