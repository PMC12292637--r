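test_that("latent feature pooling matches explicit loops and shapes", {
  z <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  expect_length(latentFeatures(z, "flatten"), 1024)
  mp <- latentFeatures(z, "mean-pool")
  expect_length(mp, 16)
  # oracle loop over all h*w positions
  oracle <- numeric(16)
  for (c in 1:16) {
    acc <- 0
    for (i in 1:8) for (j in 1:8) acc <- acc + z[i, j, c]
    oracle[c] <- acc / 64
  }
  expect_equal(mp, oracle)
  # constant grid mean-pools to the constant vector
  zc <- array(rep(1:4, each = 4), c(2, 2, 4))
  expect_equal(latentFeatures(zc, "mean-pool"), as.numeric(1:4))
  expect_error(latentFeatures(z, "max-pool"))
})

test_that("the mutual-information objective matches direct entropy computation", {
  # perfectly confident, balanced: MI = ln 2
  conf <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1), 4, 2, byrow = TRUE)
  r <- miObjective(conf)
  expect_equal(r$hMarginal, log(2))
  expect_equal(r$hConditional, 0)
  expect_equal(r$mutualInfo, log(2))
  # uninformative: MI = 0
  expect_equal(miObjective(matrix(0.5, 5, 2))$mutualInfo, 0)
  # oracle recomputation on random simplex rows
  P <- randomAssignment(10, 3, seed = 4)
  r2 <- miObjective(P)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hm <- ent(colMeans(P))
  hc <- mean(apply(P, 1, ent))
  expect_equal(r2$mutualInfo, hm - hc, tolerance = 1e-10)
  # bounds: 0 <= MI <= ln K for many random assignments
  for (s in 1:25) {
    K <- sample(2:6, 1)
    mi <- miObjective(randomAssignment(12, K, seed = s))$mutualInfo
    expect_gte(mi, 0)
    expect_lte(mi, log(K) + 1e-9)
  }
  expect_error(miObjective(matrix(c(0.7, 0.6), 1)), "sum to 1")
})

test_that("the SAT loss is a mean KL divergence with the right zeros", {
  P <- randomAssignment(6, 3, seed = 2)
  expect_equal(satLoss(P, P), 0)
  # point mass vs uniform: KL = ln 2
  expect_equal(satLoss(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)), log(2),
               tolerance = 1e-9)
  for (s in 1:20) {
    a <- randomAssignment(5, 4, seed = s)
    b <- randomAssignment(5, 4, seed = s + 100)
    expect_gte(satLoss(a, b), 0)
  }
  expect_error(satLoss(P, P[1:3, ]), "identical shape")
})

test_that("hard labels are argmax with lowest-index tie-break in [0, K)", {
  expect_equal(hardLabels(matrix(c(0.1, 0.7, 0.2), 1)), 1L)
  expect_equal(hardLabels(matrix(c(0.5, 0.5), 1)), 0L)
  P <- randomAssignment(30, 4, seed = 8)
  labs <- hardLabels(P)
  expect_true(all(labs >= 0 & labs < 4))
  # permutation equivariance: permuting rows permutes labels identically
  perm <- withr::with_seed(3, sample(30))
  expect_equal(hardLabels(P[perm, ]), labs[perm])
})

test_that("information-maximization training recovers separable structure", {
  # two well-separated copies of a cloud: balanced marginal near 1/2
  withr::with_seed(11, {
    cloud <- matrix(rnorm(40 * 4), 40, 4)
    X <- rbind(cloud, cloud + 60)
  })
  r <- trainClustering(X, 2, iters = 200, seed = 1)
  expect_lt(abs(mean(colMeans(r$probs)) - 0.5), 1e-6)
  expect_true(all(abs(colMeans(r$probs) - 0.5) < 0.05))
  # MI rises over training and respects its bound
  expect_gt(tail(r$trace$mutual_info, 1), r$trace$mutual_info[1])
  expect_lte(max(r$trace$mutual_info), log(2) + 1e-9)
  # tight 3-blob recovery
  withr::with_seed(12, {
    centers <- matrix(rnorm(3 * 6), 3, 6) * 10
    X3 <- centers[rep(1:3, each = 30), ] + matrix(rnorm(90 * 6, sd = 0.05),
                                                  90, 6)
  })
  r3 <- trainClustering(X3, 3, iters = 250, seed = 2)
  truth <- rep(1:3, each = 30)
  # label-permutation-invariant agreement
  tab <- table(r3$labels, truth)
  expect_equal(sum(apply(tab, 2, max)), 90)
  expect_error(trainClustering(X3[1:2, ], 3), "n >= K")
})

test_that("SAT training keeps augmented assignments consistent", {
  withr::with_seed(5, {
    X <- rbind(matrix(rnorm(30 * 4), 30, 4),
               matrix(rnorm(30 * 4), 30, 4) + 20)
    aug <- X + matrix(rnorm(60 * 4, sd = 0.05), 60, 4)
  })
  r <- trainClustering(X, 2, augmented = aug, muSat = 1, iters = 200,
                       seed = 3)
  pAug <- softAssign(r$head, aug)
  expect_lt(satLoss(r$probs, pAug), 0.05)
  expect_equal(hardLabels(pAug), r$labels)
})

test_that("tile augmentation preserves shape, range and determinism", {
  tile <- randomTile(16, seed = 6)
  a1 <- augmentTile(tile, seed = 9)
  expect_equal(dim(a1), dim(tile))
  expect_true(all(a1 >= 0 & a1 <= 1))
  expect_identical(a1, augmentTile(tile, seed = 9))
})
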