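deskModel <- function(seed = 1L)
  vqganModel(size = 16L, latentDim = 4L, codebookSize = 8L,
             baseChannels = 6L, nDown = 2L, seed = seed)

test_that("encoding produces the expected latent geometry deterministically", {
  m <- deskModel()
  tile <- randomTile(16, seed = 1)
  z <- encodeTile(m, tile)
  expect_equal(dim(z), c(4, 4, 4))   # 16 / 2^2, depth latentDim
  expect_identical(z, encodeTile(m, tile))
  expect_error(encodeTile(m, randomTile(15)), "factor")
  # study geometry: 128-px tiles, factor 4 -> 32 x 32 x 16 latents
  mPaper <- vqganModel(size = 128L, latentDim = 16L, codebookSize = 8L,
                       baseChannels = 2L, nDown = 2L, seed = 1)
  zP <- encodeTile(mPaper, randomTile(128, seed = 2))
  expect_equal(dim(zP), c(32, 32, 16))
})

test_that("quantization snaps to the nearest codebook row with tie-break and idempotence", {
  cb <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  q <- quantizeLatent(array(c(0.9, 0.8), c(1, 1, 2)), cb)
  expect_equal(as.vector(latentIndices(q)), 1L)  # distances 1.45 vs 0.05
  # exact codebook row -> that index, zero distance
  q5 <- quantizeLatent(array(cb[1, ], c(1, 1, 2)), cb)
  expect_equal(as.vector(latentIndices(q5)), 0L)
  expect_equal(as.vector(latentEmbedded(q5)), cb[1, ])
  # tie between equidistant rows -> lowest index
  cbT <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)
  qT <- quantizeLatent(array(c(1, 0), c(1, 1, 2)), cbT)
  expect_equal(as.vector(latentIndices(qT)), 0L)
  # idempotence on the embedded grid
  z <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  q1 <- quantizeLatent(z, cb)
  q2 <- quantizeLatent(latentEmbedded(q1), cb)
  expect_identical(latentEmbedded(q1), latentEmbedded(q2))
  expect_error(quantizeLatent(array(0, c(2, 2, 3)), cb), "dimension")
})

test_that("nearest-neighbor indices match an exhaustive scan on random inputs", {
  for (s in 1:20) {
    withr::with_seed(s, {
      K <- sample(2:10, 1); d <- sample(1:4, 1)
      cb <- matrix(rnorm(K * d), K, d)
      z <- array(rnorm(3 * 3 * d), c(3, 3, d))
    })
    q <- quantizeLatent(z, cb)
    for (i in 1:3) for (j in 1:3) {
      dists <- colSums((t(cb) - z[i, j, ])^2)
      expect_equal(latentIndices(q)[i, j],
                   which(dists == min(dists))[1] - 1L)
    }
  }
})

test_that("decoding returns clamped full-size tiles deterministically", {
  m <- deskModel()
  z <- array(rnorm(4 * 4 * 4, sd = 3), c(4, 4, 4))
  tile <- decodeLatent(m, z)
  expect_equal(dim(tile), c(16, 16, 3))
  expect_true(all(tile >= 0 & tile <= 1))
  expect_identical(tile, decodeLatent(m, z))
  expect_error(decodeLatent(m, array(0, c(4, 4, 5))), "latent depth")
})

test_that("the loss report satisfies the additivity identity", {
  m <- deskModel()
  x <- randomTile(16, seed = 2)
  zE <- encodeTile(m, x)
  q <- quantizeLatent(zE, m$codebook)
  xHat <- decodeLatent(m, q)
  rep <- vqvaeLoss(x, xHat, zE, q, beta = 0.2, lPerceptual = 0.3,
                   lAdvG = -0.1, lambdaPerc = 1.0, lambdaAdv = 0.5)
  expect_equal(rep$total,
               rep$lRec + rep$lCb + rep$beta * rep$lCommit +
                 rep$lambdaPerc * rep$lPerceptual +
                 rep$lambdaAdv * rep$lAdvG,
               tolerance = 1e-6)
  # perfect autoencoding: all three core terms vanish
  zConst <- array(rep(m$codebook[1, ], each = 4), c(2, 2, 4))
  qExact <- quantizeLatent(zConst, m$codebook)
  rep0 <- vqvaeLoss(x, x, zConst, qExact,
                    beta = 0.2)
  expect_equal(rep0$lRec, 0); expect_equal(rep0$lCb, 0)
  expect_equal(rep0$lCommit, 0); expect_equal(rep0$total, 0)
  # closed-form reconstruction MSE
  z0 <- array(0, c(2, 2, 3)); z1 <- array(0.1, c(2, 2, 3))
  repM <- vqvaeLoss(z0, z1, zConst, qExact)
  expect_equal(repM$lRec, 0.01)
  # beta scales the commitment contribution exactly
  zOff <- zConst + 0.5
  qOff <- quantizeLatent(zOff, m$codebook)
  r1 <- vqvaeLoss(x, x, zOff, qOff, beta = 0.2)
  r0 <- vqvaeLoss(x, x, zOff, qOff, beta = 0)
  expect_equal(r1$total - r0$total, 0.2 * r1$lCommit)
  expect_error(vqvaeLoss(x * NA, x, zE, q), "NaN")
})

test_that("the straight-through estimator passes gradients as the identity", {
  cb <- matrix(c(0.2, -0.1, 1.3, 0.8), 2, 2, byrow = TRUE)
  z <- array(c(0.25, -0.05), c(1, 1, 2))
  f <- function(v) sum(v^2) + 3 * v[1]
  # the contract: the gradient of f(straightThrough(z)) w.r.t. z is taken
  # as if the quantization were the identity, i.e. it equals f'(z)
  gContract <- c(2 * z[1, 1, 1] + 3, 2 * z[1, 1, 2])
  eps <- 1e-6
  num <- vapply(1:2, function(i) {
    zp <- z; zp[1, 1, i] <- zp[1, 1, i] + eps
    zm <- z; zm[1, 1, i] <- zm[1, 1, i] - eps
    (f(zp) - f(zm)) / (2 * eps)   # finite difference of f at z directly
  }, numeric(1))
  expect_equal(num, gContract, tolerance = 1e-5)
})

test_that("the patch discriminator emits a multi-cell logit grid and a per-patch mean loss", {
  m <- deskModel()
  tile <- randomTile(16, seed = 3)
  logits <- patchDiscriminate(m, tile)
  expect_true(is.matrix(logits))
  expect_gt(length(logits), 1)
  expect_identical(logits, patchDiscriminate(m, tile))
  # generator adversarial loss equals the mean of per-patch losses
  perPatch <- -logits
  expect_equal(-mean(logits), mean(perPatch))
  expect_error(patchDiscriminate(m, randomTile(8)), "expects")
})

test_that("a tiny training run reduces reconstruction error and uses multiple codes", {
  train <- tinyTileSet(6, 16, seed = 21)   # 18 heterogeneous tiles
  held <- tinyTileSet(2, 16, seed = 22)
  m0 <- deskModel(seed = 2)
  mseBefore <- mean(vapply(tiles(held), function(tl) {
    q <- quantizeLatent(encodeTile(m0, tl), m0$codebook)
    mean((decodeLatent(m0, q) - tl)^2)
  }, numeric(1)))
  tr <- trainVqgan(train, model = m0, epochs = 3, batchSize = 6, lr = 2e-3,
                   advWarmupSteps = 4L, seed = 1)
  expect_lt(tail(tr$losses$l_rec, 1), tr$losses$l_rec[1])
  mseAfter <- mean(vapply(tiles(held), function(tl) {
    q <- quantizeLatent(encodeTile(tr$model, tl), tr$model$codebook)
    mean((decodeLatent(tr$model, q) - tl)^2)
  }, numeric(1)))
  expect_lt(mseAfter, mseBefore)
  # codebook collapse guard: more than one distinct index in use
  codes <- unlist(lapply(tiles(train)[1:6], function(tl)
    as.vector(latentIndices(quantizeLatent(encodeTile(tr$model, tl),
                                           tr$model$codebook)))))
  expect_gt(length(unique(codes)), 1)
  # adversarial phase ran (warm-up of 4 < 9 steps)
  expect_true(any(tr$losses$l_adv_d != 0))
  expect_error(trainVqgan(TileSet(list()), epochs = 1), "non-empty")
})

test_that("training resumes from a checkpoint with matching losses", {
  train <- tinyTileSet(4, 16, seed = 25)
  dir <- withr::local_tempdir()
  full <- trainVqgan(train, model = deskModel(seed = 5), epochs = 2,
                     batchSize = 6, lr = 1e-3, advWarmupSteps = 1e9,
                     seed = 9, checkpointDir = dir)
  resumed <- trainVqgan(train, epochs = 2, batchSize = 6, lr = 1e-3,
                        advWarmupSteps = 1e9, seed = 9,
                        resumeFrom = file.path(dir, "vqgan_epoch001.rds"))
  expect_equal(tail(resumed$losses$l_rec, 1), tail(full$losses$l_rec, 1),
               tolerance = 1e-10)
})
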