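test_that("the linear schedule satisfies its conservation identities", {
  s <- linearSchedule(2, 0.1, 0.3)
  expect_equal(s@betas, c(0.1, 0.3))
  expect_equal(s@alphas, c(0.9, 0.7))
  expect_equal(s@alphaBars, c(0.9, 0.63))
  s1 <- linearSchedule(1, 0.25, 0.25)
  expect_equal(s1@alphaBars, 0.75)
  sT <- linearSchedule(1000, 1e-4, 0.02)
  expect_lt(sT@alphaBars[1000], 0.01)
  expect_lt(max(abs(sT@alphas + sT@betas - 1)), 1e-12)
  expect_lt(max(abs(sT@alphaBars[-1] / sT@alphaBars[-1000] -
                      sT@alphas[-1])), 1e-12)
  expect_true(all(diff(sT@betas) > 0))
  expect_true(all(diff(sT@alphaBars) < 0))
  expect_error(linearSchedule(0), "nSteps")
  expect_error(linearSchedule(10, 0.5, 0.2), "betaStart")
})

test_that("q_sample follows the closed-form marginal and its moment law", {
  s <- linearSchedule(10, 0.02, 0.4)
  # noiseless branch: scaling by sqrt(alphaBar_t)
  sFake <- linearSchedule(2, 0.1, 0.3)
  z0 <- array(1, c(2, 2, 1))
  expect_equal(qSample(z0, 1, array(0, c(2, 2, 1)), sFake),
               array(sqrt(0.9), c(2, 2, 1)))
  # variance law: Var[z_t] = 1 - alphaBar_t for z0 = 0
  withr::with_seed(1, {
    for (t in c(2L, 6L, 10L)) {
      draws <- replicate(10000, qSample(0, t, rnorm(1), s))
      v <- var(draws)
      se <- sqrt(2 / (length(draws) - 1)) * (1 - s@alphaBars[t])
      expect_lt(abs(v - (1 - s@alphaBars[t])), 4 * se)
    }
  })
  # terminal decorrelation at paper scale
  sT <- linearSchedule(1000, 1e-4, 0.02)
  withr::with_seed(2, {
    z0v <- rnorm(2000)
    zT <- sqrt(sT@alphaBars[1000]) * z0v + sqrt(1 - sT@alphaBars[1000]) *
      rnorm(2000)
    expect_lt(abs(cor(zT, z0v)), 0.2)
  })
  expect_error(qSample(z0, 11, z0, s), "t must lie")
})

test_that("the denoising loss is the symmetric elementwise MSE", {
  a <- array(rnorm(8), c(2, 2, 2))
  expect_equal(denoiseLoss(a, a), 0)
  expect_equal(denoiseLoss(array(0, c(2, 2)), array(0.1, c(2, 2))), 0.01)
  b <- array(rnorm(8), c(2, 2, 2))
  expect_equal(denoiseLoss(a, b), denoiseLoss(b, a))
  expect_error(denoiseLoss(a, a * NA), "NaN")
})

test_that("one reverse step with the true noise inverts q_sample exactly at t = 1", {
  s <- linearSchedule(2, 0.1, 0.3)
  z0 <- array(1, c(1, 1, 1))
  eps <- array(0.5, c(1, 1, 1))
  z1 <- qSample(z0, 1, eps, s)
  expect_equal(as.vector(z1), sqrt(0.9) + sqrt(0.1) * 0.5, tolerance = 1e-12)
  oracle <- function(z, t, c) eps
  back <- pSampleStep(z1, 1L, 0L, oracle, s)
  expect_equal(as.vector(back), 1, tolerance = 1e-9)
  # zero net, zero latent: the posterior mean is the fixed point 0
  zeroNet <- function(z, t, c) array(0, dim(z))
  expect_equal(as.vector(pSampleStep(array(0, c(1, 1, 1)), 1L, 0L, zeroNet,
                                     s)), 0)
  expect_error(pSampleStep(z1, 5L, 0L, oracle, s), "t must lie")
})

test_that("denoiser gradients match finite differences", {
  net <- makeDenoiser(2, 3, channels = 4, embDim = 8, nDown = 1, seed = 3)
  x <- withr::with_seed(2, array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2)))
  tt <- c(1, 7); cond <- c(0L, 2L)
  lossOf <- function(n) {
    fw <- HistoCLDM:::denoiserForward(n, x, tt, cond)
    sum(fw$out^2) / 2
  }
  fw <- HistoCLDM:::denoiserForward(net, x, tt, cond, keepCaches = TRUE)
  g <- HistoCLDM:::denoiserBackward(net, fw$out, fw$cache)
  eps <- 1e-5
  checkLeaf <- function(getter, setter, gLeaf) {
    v <- getter(net)
    for (i in withr::with_seed(1, sample(length(v), min(4, length(v))))) {
      np <- setter(net, replace(v, i, v[i] + eps))
      nm <- setter(net, replace(v, i, v[i] - eps))
      num <- (lossOf(np) - lossOf(nm)) / (2 * eps)
      expect_equal(num, gLeaf[i], tolerance = 1e-5)
    }
  }
  checkLeaf(function(n) n$classEmb,
            function(n, v) { n$classEmb[] <- v; n }, g$classEmb)
  checkLeaf(function(n) n$projIn$W,
            function(n, v) { n$projIn$W[] <- v; n }, g$projIn$W)
  checkLeaf(function(n) n$down[[1]]$conv$W,
            function(n, v) { n$down[[1]]$conv$W[] <- v; n },
            g$down[[1]]$conv$W)
  checkLeaf(function(n) n$up[[1]]$res$conv2$W,
            function(n, v) { n$up[[1]]$res$conv2$W[] <- v; n },
            g$up[[1]]$res$conv2$W)
  checkLeaf(function(n) n$convOut$W,
            function(n, v) { n$convOut$W[] <- v; n }, g$convOut$W)
})

test_that("sampling is seed-reproducible and emits valid tiles", {
  net <- makeDenoiser(2, 2, channels = 4, embDim = 8, nDown = 1, seed = 1)
  s <- linearSchedule(10, 0.01, 0.3)
  z1 <- sampleLatents(2, 0L, net, s, c(4, 4, 2), seed = 1)
  z1b <- sampleLatents(2, 0L, net, s, c(4, 4, 2), seed = 1)
  z2 <- sampleLatents(2, 0L, net, s, c(4, 4, 2), seed = 2)
  expect_identical(z1, z1b)
  expect_false(identical(z1, z2))
  # untrained net still completes and yields in-range tiles end to end
  vq <- vqganModel(size = 16L, latentDim = 2L, codebookSize = 4L,
                   baseChannels = 4L, nDown = 2L, seed = 2)
  ldm <- structure(list(net = net, schedule = s, latentShape = c(4, 4, 2),
                        shift = 0, scale = 1), class = "LatentDiffusion")
  ts <- sampleTiles(ldm, vq, 2, 1L, seed = 3)
  expect_s4_class(ts, "TileSet")
  expect_equal(length(ts), 2L)
  for (tl in tiles(ts)) expect_true(all(tl >= 0 & tl <= 1))
})

test_that("three-phase training reduces the loss and honors the freeze contract", {
  withr::with_seed(4, {
    lats <- lapply(1:16, function(i) {
      cl <- (i - 1) %/% 8
      array(rnorm(4 * 4 * 2, mean = c(-1.5, 1.5)[cl + 1], sd = 0.3),
            c(4, 4, 2))
    })
  })
  conds <- rep(0:1, each = 8)
  head0 <- clusterHead(2, 2, hidden = 8, seed = 5)
  feats <- t(vapply(lats, function(z) apply(z, 3, mean), numeric(2)))
  phases <- ldmPhases(epochs = c(25L, 5L, 5L), lrs = c(1.0, 1e-3, 1.0))
  r <- trainLDM(lats, conds, K = 2, phases = phases,
                schedule = linearSchedule(20, 0.01, 0.4), batchSize = 8,
                channels = 8, embDim = 8, nDown = 1, head = head0,
                features = feats, augmented = feats, seed = 6)
  expect_lt(tail(r$losses$mse, 1), r$losses$mse[1])
  # finetune-1 freezes the clustering head bitwise
  r1 <- trainLDM(lats, conds, K = 2,
                 phases = list(list(name = "finetune1", optimizer = "adam",
                                    lr = 1e-3, epochs = 2L,
                                    freezeClusterHead = TRUE,
                                    useSat = FALSE)),
                 schedule = linearSchedule(20, 0.01, 0.4), batchSize = 8,
                 channels = 8, embDim = 8, nDown = 1, head = head0,
                 features = feats, augmented = feats, seed = 7)
  expect_identical(r1$head, head0)
  expect_error(trainLDM(lats, conds[1:3], K = 2), "align")
  expect_error(trainLDM(lats, conds + 5L, K = 2), "\\[0, K\\)")
})

test_that("conditional fidelity scores match a direct confusion computation", {
  vq <- vqganModel(size = 16L, latentDim = 4L, codebookSize = 8L,
                   baseChannels = 6L, nDown = 2L, seed = 8)
  ds <- tinyTileSet(3, 16, seed = 44)
  feats <- t(vapply(tiles(ds), function(tl)
    latentFeatures(quantizeLatent(encodeTile(vq, tl), vq$codebook)),
    numeric(4)))
  # a head biased to always answer cluster 1: accuracy 1 for intended = 1
  biased <- clusterHead(4, 3, hidden = 4, seed = 9)
  biased$W1[] <- 0; biased$W2[] <- 0
  biased$b2 <- c(-10, 10, -10)
  fid1 <- conditionalFidelity(ds, rep(1L, length(ds)), vq, biased)
  expect_equal(fid1$overall, 1)
  expect_equal(fid1$table$accuracy, 1)
  # partition: per-cluster counts sum to the total
  intended <- rep(0:2, each = 3)
  fid <- conditionalFidelity(ds, intended, vq, biased)
  expect_equal(sum(fid$table$n), length(ds))
  # biased head vs balanced intended IDs: overall accuracy is 1/K
  expect_equal(fid$overall, 1 / 3, tolerance = 1e-9)
  expect_error(conditionalFidelity(ds, intended[1:2], vq, biased), "align")
})
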