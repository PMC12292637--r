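test_that("ssim satisfies identity, symmetry, boundedness and the constant-image closed form", {
  for (s in 1:5) {
    x <- randomTile(16, seed = s)
    y <- randomTile(16, seed = s + 100)
    expect_equal(ssim(x, x), 1)
    expect_equal(ssim(x, y), ssim(y, x))
    expect_lte(abs(ssim(x, y)), 1)
  }
  # constant images: variance terms cancel, luminance-only closed form
  a <- array(0.5, c(16, 16, 3)); b <- array(0.25, c(16, 16, 3))
  expected <- (2 * 0.5 * 0.25 + 1e-4) / (0.25 + 0.0625 + 1e-4)
  expect_equal(ssim(a, b), expected, tolerance = 1e-4)
  # inverting a checkerboard degrades similarity
  cb <- array(rep(c(0, 1), length.out = 16 * 16), c(16, 16, 1))
  expect_lt(ssim(cb, 1 - cb), ssim(cb, cb))
  expect_error(ssim(a, array(0.5, c(8, 8, 3))), "identical dimensions")
})

test_that("ms-ssim reduces to ssim at a single scale and renormalizes dropped weights", {
  x <- randomTile(32, seed = 3)
  y <- randomTile(32, seed = 4)
  expect_equal(msSsim(x, x), 1)
  expect_equal(msSsim(x, y, weights = 1), ssim(x, y), tolerance = 1e-6)
  # 32 px supports only 3 of the default 5 scales (>= 8 px each)
  v <- msSsim(x, y)
  expect_true(is.finite(v) && v >= 0 && v <= 1)
  expect_equal(msSsim(x, y),
               msSsim(x, y, weights = c(0.0448, 0.2856, 0.3001)))
})

test_that("the perceptual distance is zero at identity, symmetric and non-negative", {
  ex <- randomFeatureExtractor(seed = 2)
  for (s in 1:10) {
    x <- randomTile(16, seed = s)
    y <- randomTile(16, seed = s + 50)
    expect_equal(perceptualDistance(x, x, ex), 0)
    d <- perceptualDistance(x, y, ex)
    expect_gte(d, 0)
    expect_equal(d, perceptualDistance(y, x, ex))
  }
  # repeated application yields identical features (frozen contract)
  x <- randomTile(16, seed = 1)
  expect_identical(ex$apply(x), ex$apply(x))
})

test_that("the perceptual distance matches a hand evaluation under an identity extractor", {
  idEx <- customFeatureExtractor(
    function(img) list(img),
    layers = list(list(name = "identity", channels = 1L)))
  x <- array(c(0.2, 0.4, 0.6, 0.8), c(2, 2, 1))
  y <- array(c(0.8, 0.6, 0.4, 0.2), c(2, 2, 1))
  # one channel: unit-normalized maps are x/(|x| + eps); expected value is
  # the spatial mean of squared differences of those maps
  nx <- x / (abs(x) + 1e-10)
  ny <- y / (abs(y) + 1e-10)
  expect_equal(perceptualDistance(x, y, idEx), mean((nx - ny)^2),
               tolerance = 1e-8)
  # lpipsMetric is the same computation
  ex <- randomFeatureExtractor(seed = 5)
  a <- randomTile(16, seed = 7); b <- randomTile(16, seed = 8)
  expect_equal(lpipsMetric(a, b, ex), perceptualDistance(a, b, ex),
               tolerance = 1e-8)
})

test_that("evaluateGeneration aggregates per-pair metrics and records n_pairs", {
  ds <- tinyTileSet(2, 16, seed = 31)
  ex <- randomFeatureExtractor(seed = 3)
  selfRep <- evaluateGeneration(ds, ds, extractor = ex, k = 3L)
  expect_equal(selfRep$ssim, 1)
  expect_equal(selfRep$ms_ssim, 1)
  expect_equal(selfRep$lpips, 0)
  expect_equal(selfRep$n_pairs, length(ds))

  other <- tinyTileSet(2, 16, seed = 32)
  rep <- evaluateGeneration(ds, other, extractor = ex)
  # aggregation oracle: recompute the means pair by pair
  ss <- mapply(function(a, b) ssim(a, b), tiles(ds), tiles(other))
  ms <- mapply(function(a, b) msSsim(a, b), tiles(ds), tiles(other))
  lp <- mapply(function(a, b) perceptualDistance(a, b, ex), tiles(ds),
               tiles(other))
  expect_equal(rep$ssim, mean(ss))
  expect_equal(rep$ms_ssim, mean(ms))
  expect_equal(rep$lpips, mean(lp))
  expect_error(evaluateGeneration(ds, other[1:3]), "equal dataset sizes")
})

test_that("best-cluster-set selection follows majority rule with smallest-k ties", {
  mk <- function(k, s, m, l) data.frame(k = k, ssim = s, ms_ssim = m,
                                        lpips = l, n_pairs = 10)
  r <- rbind(mk(10, 0.9, 0.8, 0.5), mk(12, 0.7, 0.6, 0.1))
  expect_equal(selectBestClusterSet(r)$k, 10)    # 2 votes vs 1
  r3 <- rbind(mk(10, 0.9, 0.1, 0.9), mk(11, 0.1, 0.9, 0.8),
              mk(12, 0.2, 0.2, 0.1))
  expect_equal(selectBestClusterSet(r3)$k, 10)   # 1-1-1 tie -> smallest
  # permutation invariance
  expect_equal(selectBestClusterSet(r3[c(2, 3, 1), ])$k, 10)
  expect_error(selectBestClusterSet(rbind(mk(5, 1, 1, 1), mk(5, 2, 2, 2))),
               "duplicate")
})
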