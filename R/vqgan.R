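## Vector-quantized autoencoder with adversarial and perceptual training.
##
## The encoder maps a [0,1] RGB tile (rescaled to [-1,1] at the model
## boundary) through strided convolutions with residual blocks and SiLU
## activations to an h x w x d latent grid; each latent vector is snapped to
## its nearest codebook row; the decoder mirrors the encoder and ends in a
## tanh, so outputs land in [0,1] after inverse rescaling. Training combines
## the reconstruction MSE, the codebook and commitment terms (commitment
## weight beta, default 0.2), a perceptual feature distance, and a
## patch-level hinge adversarial loss (PatchGAN discriminator; hinge for the
## discriminator, -mean(logits) for the generator). The codebook receives
## gradients through the codebook loss term; the quantization bottleneck is
## bridged with the straight-through estimator.

#' Construct a VQ-GAN model
#'
#' Defaults mirror the study-scale configuration (128-px tiles, 32 x 32
#' latent grid of dimension 16, codebook of 128 vectors, commitment weight
#' 0.2); tests use a reduced desk-scale configuration.
#'
#' @param size input tile side length; must be divisible by `2^nDown`.
#' @param latentDim codebook vector dimension d.
#' @param codebookSize number of codebook vectors K.
#' @param baseChannels channel width of the first stage.
#' @param nDown number of stride-2 downsampling stages (total factor
#'   `2^nDown`; 2 stages map 128 -> 32).
#' @param beta commitment-loss weight in [0, 1].
#' @param lambdaPerc,lambdaAdv weights of the perceptual and generator
#'   adversarial losses.
#' @param seed RNG seed for weight initialization.
#' @param extractor frozen feature extractor for the perceptual loss.
#' @return a list of class `"VqGanModel"`.
#' @export
vqganModel <- function(size = 128L, latentDim = 16L, codebookSize = 128L,
                       baseChannels = 16L, nDown = 2L, beta = 0.2,
                       lambdaPerc = 1.0, lambdaAdv = 0.5, seed = 1L,
                       extractor = NULL) {
  factor <- 2L^nDown
  if (size %% factor != 0L)
    stop("invalid argument: tile size ", size,
         " is not divisible by the downsampling factor ", factor)
  if (beta < 0 || beta > 1)
    stop("invalid argument: beta must lie in [0, 1]")
  c1 <- baseChannels
  c2 <- 2L * baseChannels
  model <- withr::with_seed(as.integer(seed), {
    enc <- list(makeConv(3L, 3L, c1), list(type = "silu"), makeResBlock(c1),
                makeConv(4L, c1, c2, stride = 2L, pad = 1L),
                list(type = "silu"), makeResBlock(c2))
    if (nDown >= 2L) for (i in seq_len(nDown - 1L)) {
      enc <- c(enc, list(makeConv(4L, c2, c2, stride = 2L, pad = 1L),
                         list(type = "silu"), makeResBlock(c2)))
    }
    enc <- c(enc, list(makeConv(3L, c2, latentDim)))
    dec <- list(makeConv(3L, latentDim, c2), list(type = "silu"),
                makeResBlock(c2))
    if (nDown >= 2L) for (i in seq_len(nDown - 1L)) {
      dec <- c(dec, list(list(type = "up"), makeConv(3L, c2, c2),
                         list(type = "silu"), makeResBlock(c2)))
    }
    dec <- c(dec, list(list(type = "up"), makeConv(3L, c2, c1),
                       list(type = "silu"), makeResBlock(c1),
                       makeConv(3L, c1, 3L), list(type = "tanh")))
    disc <- list(makeConv(4L, 3L, c1, stride = 2L, pad = 1L),
                 list(type = "silu"),
                 makeConv(4L, c1, c2, stride = 2L, pad = 1L),
                 list(type = "silu"),
                 makeConv(3L, c2, 1L))
    codebook <- matrix(stats::runif(codebookSize * latentDim, -1, 1) /
                         latentDim, codebookSize, latentDim)
    list(enc = enc, dec = dec, disc = disc, codebook = codebook)
  })
  if (is.null(extractor))
    extractor <- randomFeatureExtractor(seed = as.integer(seed) + 1000L)
  structure(list(
    enc = model$enc, dec = model$dec, disc = model$disc,
    codebook = model$codebook, extractor = extractor,
    config = list(size = as.integer(size), latentDim = as.integer(latentDim),
                  codebookSize = as.integer(codebookSize),
                  baseChannels = as.integer(baseChannels),
                  nDown = as.integer(nDown), factor = factor, beta = beta,
                  lambdaPerc = lambdaPerc, lambdaAdv = lambdaAdv,
                  seed = as.integer(seed))
  ), class = "VqGanModel")
}

#' @export
print.VqGanModel <- function(x, ...) {
  cf <- x$config
  cat(sprintf(
    "VqGanModel: %d-px tiles -> %dx%dx%d latents, codebook %d x %d, beta %.2g\n",
    cf$size, cf$size %/% cf$factor, cf$size %/% cf$factor, cf$latentDim,
    cf$codebookSize, cf$latentDim, cf$beta))
  invisible(x)
}

#' Encode tiles to continuous latent grids
#'
#' The tile is rescaled to [-1, 1] and pushed through the frozen-or-current
#' encoder. Deterministic for fixed parameters.
#'
#' @param model a [vqganModel()].
#' @param x one `H x W x 3` tile, or a [TileSet-class].
#' @return an `h x w x d` latent array (`h = size / 2^nDown`), or a list of
#'   them for a `TileSet`.
#' @export
encodeTile <- function(model, x) {
  if (is(x, "TileSet"))
    return(lapply(tiles(x), function(t) encodeTile(model, t)))
  d <- dim(x)
  if (d[1] %% model$config$factor != 0L)
    stop("invalid argument: tile size ", d[1],
         " is not divisible by the downsampling factor ", model$config$factor)
  x4 <- array(2 * x - 1, c(d, 1L))
  out <- seqForward(x4, model$enc)$out
  out[, , , 1L, drop = TRUE]
}

#' Quantize a latent grid against a codebook
#'
#' Each latent vector maps to the codebook row with minimum squared
#' Euclidean distance; ties break toward the lowest index. The embedded grid
#' is exactly the codebook lookup of the indices.
#'
#' @param latent `h x w x d` numeric array.
#' @param codebook a [Codebook-class] or a plain K x d matrix.
#' @return a [QuantizedLatent-class].
#' @export
quantizeLatent <- function(latent, codebook) {
  E <- if (is(codebook, "Codebook")) codebookVectors(codebook) else codebook
  d <- dim(latent)
  if (d[3] != ncol(E))
    stop("invalid argument: latent depth ", d[3],
         " does not match codebook dimension ", ncol(E))
  Z <- matrix(latent, d[1] * d[2], d[3])
  ## squared distances ||z||^2 - 2 z.e + ||e||^2; ||z||^2 constant per row
  D <- -2 * Z %*% t(E) + rep(rowSums(E^2), each = nrow(Z))
  idx <- max.col(-D, ties.method = "first")
  emb <- E[idx, , drop = FALSE]
  new("QuantizedLatent",
      indices = matrix(as.integer(idx - 1L), d[1], d[2]),
      embedded = array(emb, d))
}

#' Straight-through quantization
#'
#' Returns the embedded (quantized) latent; by the straight-through
#' estimator the gradient of any scalar function of the result with respect
#' to the input latent is taken as if the quantization were the identity.
#' Training uses this contract to pass decoder gradients through the
#' codebook bottleneck unchanged.
#'
#' @inheritParams quantizeLatent
#' @return the `h x w x d` embedded array.
#' @export
straightThrough <- function(latent, codebook) {
  latentEmbedded(quantizeLatent(latent, codebook))
}

#' Decode a quantized latent to a tile
#'
#' @param model a [vqganModel()].
#' @param q a [QuantizedLatent-class] or an `h x w x d` latent array.
#' @return an `H x W x 3` tile in [0, 1] (tanh output mapped from [-1, 1]
#'   and clamped).
#' @export
decodeLatent <- function(model, q) {
  z <- if (is(q, "QuantizedLatent")) latentEmbedded(q) else q
  d <- dim(z)
  if (d[3] != model$config$latentDim)
    stop("invalid argument: latent depth ", d[3], " does not match model (",
         model$config$latentDim, ")")
  z4 <- array(z, c(d, 1L))
  out <- seqForward(z4, model$dec)$out
  tile <- (out[, , , 1L, drop = TRUE] + 1) / 2
  tile[tile < 0] <- 0
  tile[tile > 1] <- 1
  tile
}

#' Reconstruct tiles through the full encode-quantize-decode path
#'
#' @param model a [vqganModel()].
#' @param dataset a [TileSet-class].
#' @return a [TileSet-class] of reconstructions (same ids/labels).
#' @export
reconstructTiles <- function(model, dataset) {
  rec <- lapply(tiles(dataset), function(t) {
    q <- quantizeLatent(encodeTile(model, t), model$codebook)
    decodeLatent(model, q)
  })
  TileSet(rec, ids = tileIds(dataset), labels = tileLabels(dataset),
          split = dataset@split)
}

#' Patch-level discriminator logits
#'
#' Applies the PatchGAN discriminator; each logit corresponds to one
#' receptive-field patch of the input, so model-size inputs produce a grid
#' with more than one cell.
#'
#' @param model a [vqganModel()].
#' @param tile `H x W x 3` array in [0, 1].
#' @return a numeric matrix of patch logits.
#' @export
patchDiscriminate <- function(model, tile) {
  d <- dim(tile)
  if (d[1] != model$config$size)
    stop("invalid argument: discriminator expects ", model$config$size,
         "-px tiles, got ", d[1])
  x4 <- array(2 * tile - 1, c(d, 1L))
  out <- seqForward(x4, model$disc)$out
  matrix(out[, , 1L, 1L], dim(out)[1], dim(out)[2])
}

#' VQ-VAE loss report
#'
#' Computes the three autoencoding terms: reconstruction MSE between the
#' tiles, the codebook term (mean squared distance between the
#' stop-gradient latent and its codebook vectors) and the commitment term
#' (same distance, gradient side swapped), plus optional perceptual and
#' adversarial contributions. The reported `total` is
#' `l_rec + l_cb + beta * l_commit + lambdaPerc * l_perceptual +
#' lambdaAdv * l_adv_g`.
#'
#' @param x,xHat original and reconstructed tiles (`H x W x 3`, [0, 1]).
#' @param zE continuous encoder latent (`h x w x d`).
#' @param q the [QuantizedLatent-class] of `zE`.
#' @param beta commitment weight in [0, 1].
#' @param lPerceptual,lAdvG,lAdvD optional extra loss values to fold in.
#' @param lambdaPerc,lambdaAdv weights of the extra terms.
#' @return a list of class `"VqGanLossReport"`.
#' @export
vqvaeLoss <- function(x, xHat, zE, q, beta = 0.2, lPerceptual = 0,
                      lAdvG = 0, lAdvD = 0, lambdaPerc = 1, lambdaAdv = 0.5) {
  if (anyNA(x) || anyNA(xHat) || anyNA(zE))
    stop("numeric error: NaN in loss inputs")
  if (beta < 0 || beta > 1)
    stop("invalid argument: beta must lie in [0, 1]")
  if (!identical(dim(x), dim(xHat)))
    stop("invalid argument: tile shapes disagree")
  e <- latentEmbedded(q)
  lRec <- mean((x - xHat)^2)
  lCb <- mean((zE - e)^2)      # gradient flows to the codebook
  lCommit <- mean((zE - e)^2)  # gradient flows to the encoder
  total <- lRec + lCb + beta * lCommit + lambdaPerc * lPerceptual +
    lambdaAdv * lAdvG
  structure(list(lRec = lRec, lCb = lCb, lCommit = lCommit, beta = beta,
                 lPerceptual = lPerceptual, lAdvG = lAdvG, lAdvD = lAdvD,
                 lambdaPerc = lambdaPerc, lambdaAdv = lambdaAdv,
                 total = total), class = "VqGanLossReport")
}

#' @export
print.VqGanLossReport <- function(x, ...) {
  cat(sprintf(
    "VqGanLossReport: rec %.4g + cb %.4g + %.2g*commit %.4g + %.2g*perc %.4g + %.2g*advG %.4g = %.4g\n",
    x$lRec, x$lCb, x$beta, x$lCommit, x$lambdaPerc, x$lPerceptual,
    x$lambdaAdv, x$lAdvG, x$total))
  invisible(x)
}

## ---- training ----

## One generator forward/backward on a batch; returns losses and gradients.
vqganGeneratorStep <- function(model, x4, advWeight, percWeight) {
  cf <- model$config
  N <- dim(x4)[4]
  encFw <- seqForward(2 * x4 - 1, model$enc)
  zE <- encFw$out
  dz <- dim(zE)
  hw <- dz[1] * dz[2]
  ## rows of Z are the latent vectors of the whole batch (position-major,
  ## sample blocks), columns the d latent channels
  Z <- matrix(aperm(zE, c(1, 2, 4, 3)), hw * dz[4], dz[3])
  ## nearest codebook rows for the whole batch
  E <- model$codebook
  D <- -2 * Z %*% t(E) + rep(rowSums(E^2), each = nrow(Z))
  idx <- max.col(-D, ties.method = "first")
  emb <- aperm(array(E[idx, , drop = FALSE], c(dz[1], dz[2], dz[4], dz[3])),
               c(1, 2, 4, 3))
  nLat <- length(zE)
  decFw <- seqForward(emb, model$dec)
  xHat <- (decFw$out + 1) / 2
  lRec <- mean((xHat - x4)^2)
  dxHat <- 2 * (xHat - x4) / length(x4)
  lPerc <- 0
  if (percWeight > 0) {
    for (n in seq_len(N)) {
      pg <- perceptualGrad(x4[, , , n], xHat[, , , n], model$extractor)
      lPerc <- lPerc + pg$value / N
      dxHat[, , , n] <- dxHat[, , , n] + percWeight * pg$dy / N
    }
  }
  lAdvG <- 0
  if (advWeight > 0) {
    dFw <- seqForward(2 * xHat - 1, model$disc)
    lAdvG <- -mean(dFw$out)
    dLog <- array(-1 / length(dFw$out), dim(dFw$out))
    dAdv <- seqBackward(dLog, model$disc, dFw$caches)$dx
    dxHat <- dxHat + advWeight * 2 * dAdv
  }
  decBk <- seqBackward(dxHat * 0.5, model$dec, decFw$caches)
  ## straight-through: decoder gradient passes unchanged to zE, plus the
  ## commitment pull toward the (stopped) codebook vectors
  lCommit <- mean((zE - emb)^2)
  dzE <- decBk$dx + cf$beta * 2 * (zE - emb) / nLat
  encBk <- seqBackward(dzE, model$enc, encFw$caches)
  ## codebook gradient from the codebook loss (stop-gradient on zE)
  dE <- matrix(0, nrow(E), ncol(E))
  diffM <- matrix(aperm(emb - zE, c(1, 2, 4, 3)), nrow(Z), dz[3])
  acc <- rowsum(2 * diffM / nLat, idx)
  dE[as.integer(rownames(acc)), ] <- acc
  list(lRec = lRec, lCb = lCommit, lCommit = lCommit, lPerc = lPerc,
       lAdvG = lAdvG, idx = idx, xHat = xHat,
       grads = list(enc = encBk$grads, dec = decBk$grads, codebook = dE))
}

## Discriminator hinge step on a batch of real and generated tiles.
vqganDiscStep <- function(model, xReal4, xFake4) {
  fwR <- seqForward(2 * xReal4 - 1, model$disc)
  fwF <- seqForward(2 * xFake4 - 1, model$disc)
  lR <- mean(pmax(0, 1 - fwR$out))
  lF <- mean(pmax(0, 1 + fwF$out))
  dR <- array(ifelse(fwR$out < 1, -1, 0) / length(fwR$out), dim(fwR$out))
  dF <- array(ifelse(fwF$out > -1, 1, 0) / length(fwF$out), dim(fwF$out))
  gR <- seqBackward(dR, model$disc, fwR$caches)$grads
  gF <- seqBackward(dF, model$disc, fwF$caches)$grads
  g <- gR
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    g[[i]] <- mapTree2(g[[i]], gF[[i]], `+`)
  }
  list(loss = lR + lF, grads = g)
}

## elementwise combination of two parallel numeric trees
mapTree2 <- function(a, b, fn) {
  if (is.numeric(a)) return(fn(a, b))
  if (is.list(a)) return(mapply(mapTree2, a, b, MoreArgs = list(fn = fn),
                                SIMPLIFY = FALSE))
  a
}

#' Train the VQ-GAN
#'
#' Minibatch training with Adam (study-scale defaults: learning rate 1e-4,
#' batch 16, 20 epochs). The discriminator is held out of the objective for
#' `advWarmupSteps` generator steps to avoid early adversarial collapse.
#' When `checkpointDir` is given, a checkpoint and the loss series are
#' written each epoch and training can resume from a checkpoint file.
#'
#' @param dataset a non-empty [TileSet-class].
#' @param model an existing [vqganModel()] (default: a new one sized to the
#'   data).
#' @param epochs,batchSize,lr training hyperparameters.
#' @param advWarmupSteps generator steps before the adversarial loss turns on.
#' @param seed RNG seed controlling shuffling.
#' @param checkpointDir optional directory for per-epoch checkpoints and the
#'   loss-series CSV.
#' @param resumeFrom optional checkpoint file to resume from.
#' @param verbose print per-epoch losses.
#' @param ... passed to [vqganModel()] when no model is supplied.
#' @return a list with `model` (trained) and `losses` (per-epoch
#'   `data.frame`: epoch, l_rec, l_cb, l_commit, l_perceptual, l_adv_g,
#'   l_adv_d, total).
#' @export
trainVqgan <- function(dataset, model = NULL, epochs = 20L, batchSize = 16L,
                       lr = 1e-4, advWarmupSteps = 50L, seed = 1L,
                       checkpointDir = NULL, resumeFrom = NULL,
                       verbose = FALSE, ...) {
  if (!is(dataset, "TileSet") || length(dataset) == 0L)
    stop("invalid argument: dataset must be a non-empty TileSet")
  if (is.null(model))
    model <- vqganModel(size = tileSize(dataset), seed = seed, ...)
  cf <- model$config
  genParams <- list(enc = model$enc, dec = model$dec,
                    codebook = model$codebook)
  genState <- adamInit(genParams)
  discState <- adamInit(model$disc)
  startEpoch <- 1L
  step <- 0L
  lossRows <- list()
  if (!is.null(resumeFrom)) {
    ck <- readRDS(resumeFrom)
    model <- ck$model
    genParams <- list(enc = model$enc, dec = model$dec,
                      codebook = model$codebook)
    genState <- ck$genState
    discState <- ck$discState
    startEpoch <- ck$epoch + 1L
    step <- ck$step
    lossRows <- ck$lossRows
    assign(".Random.seed", ck$rngState, envir = globalenv())
  } else {
    set.seed(as.integer(seed))
  }
  n <- length(dataset)
  tl <- tiles(dataset)
  for (ep in seq.int(startEpoch, epochs)) {
    ord <- sample.int(n)
    acc <- c(l_rec = 0, l_cb = 0, l_commit = 0, l_perceptual = 0,
             l_adv_g = 0, l_adv_d = 0)
    nb <- 0L
    for (b in seq(1L, n, by = batchSize)) {
      take <- ord[b:min(b + batchSize - 1L, n)]
      x4 <- stackTiles(tl[take])
      advOn <- step >= advWarmupSteps
      g <- vqganGeneratorStep(model, x4,
                              advWeight = if (advOn) cf$lambdaAdv else 0,
                              percWeight = cf$lambdaPerc)
      if (!is.finite(g$lRec))
        stop("non-finite loss at epoch ", ep, "; aborting")
      upd <- adamStep(genParams, g$grads, genState, lr = lr)
      genParams <- upd$params
      genState <- upd$state
      model$enc <- genParams$enc
      model$dec <- genParams$dec
      model$codebook <- genParams$codebook
      lAdvD <- 0
      if (advOn) {
        dstep <- vqganDiscStep(model, x4, g$xHat)
        lAdvD <- dstep$loss
        updD <- adamStep(model$disc, dstep$grads, discState, lr = lr)
        model$disc <- updD$params
        discState <- updD$state
      }
      acc <- acc + c(g$lRec, g$lCb, g$lCommit, g$lPerc, g$lAdvG, lAdvD)
      nb <- nb + 1L
      step <- step + 1L
    }
    acc <- acc / nb
    row <- data.frame(epoch = ep, l_rec = acc[1], l_cb = acc[2],
                      l_commit = acc[3], l_perceptual = acc[4],
                      l_adv_g = acc[5], l_adv_d = acc[6],
                      total = acc[1] + acc[2] + cf$beta * acc[3] +
                        cf$lambdaPerc * acc[4] + cf$lambdaAdv * acc[5],
                      row.names = NULL)
    lossRows[[length(lossRows) + 1L]] <- row
    if (verbose)
      message(sprintf("epoch %d: rec %.4f cb %.4f perc %.4f", ep, acc[1],
                      acc[2], acc[4]))
    if (!is.null(checkpointDir)) {
      dir.create(checkpointDir, recursive = TRUE, showWarnings = FALSE)
      saveRDS(list(model = model, genState = genState,
                   discState = discState, epoch = ep, step = step,
                   lossRows = lossRows, seed = seed,
                   rngState = get(".Random.seed", envir = globalenv())),
              file.path(checkpointDir, sprintf("vqgan_epoch%03d.rds", ep)))
      utils::write.csv(do.call(rbind, lossRows),
                       file.path(checkpointDir, "vqgan_losses.csv"),
                       row.names = FALSE)
    }
  }
  list(model = model, losses = do.call(rbind, lossRows))
}
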