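## Structural-similarity metrics (SSIM, MS-SSIM) on [0, 1] images.
## Standard parameterization: Gaussian window (sigma 1.5), stabilizers
## C1 = (k1 L)^2, C2 = (k2 L)^2 with dynamic range L = 1, k1 = 0.01,
## k2 = 0.03. Channels are scored separately and averaged.

gaussianWindow <- function(windowSize, sigma = 1.5) {
  half <- (windowSize - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g / sum(g)
}

## Valid-region separable convolution of matrix m with 1-D kernel g, both
## dimensions; implemented as banded-matrix products.
sepConvValid <- function(m, g) {
  n <- nrow(m)
  L <- length(g)
  outN <- n - L + 1L
  Tm <- matrix(0, outN, n)
  for (i in seq_len(outN)) Tm[i, i:(i + L - 1L)] <- g
  Tm %*% m %*% t(Tm)
}

## Per-channel SSIM and contrast-structure maps for one channel pair.
ssimMaps <- function(x, y, g, C1, C2) {
  mx <- sepConvValid(x, g)
  my <- sepConvValid(y, g)
  mx2 <- mx^2; my2 <- my^2; mxy <- mx * my
  sx2 <- sepConvValid(x^2, g) - mx2
  sy2 <- sepConvValid(y^2, g) - my2
  sxy <- sepConvValid(x * y, g) - mxy
  l <- (2 * mxy + C1) / (mx2 + my2 + C1)
  cs <- (2 * sxy + C2) / (sx2 + sy2 + C2)
  list(ssim = l * cs, cs = cs)
}

oddWindow <- function(windowSize, size) {
  w <- min(windowSize, size)
  if (w %% 2L == 0L) w <- w - 1L
  max(w, 1L)
}

#' Structural similarity index (SSIM)
#'
#' Windowed SSIM with a Gaussian window, averaged over window positions and
#' channels. Symmetric, bounded by 1, equal to 1 iff the images are
#' identical.
#'
#' @param x,y images as `H x W x C` arrays (or `H x W` matrices) in [0, 1],
#'   equal size.
#' @param windowSize odd window side length (shrunk automatically for small
#'   images).
#' @param k1,k2 stabilizer constants (dynamic range L = 1).
#' @param sigma Gaussian window standard deviation.
#' @return a scalar in [-1, 1].
#' @export
#' @examples
#' x <- array(runif(32 * 32 * 3), c(32, 32, 3))
#' ssim(x, x)  # 1
ssim <- function(x, y, windowSize = 11L, k1 = 0.01, k2 = 0.03, sigma = 1.5) {
  if (!identical(dim(x), dim(y)))
    stop("invalid argument: images must have identical dimensions")
  if (length(dim(x)) == 2L) { dim(x) <- c(dim(x), 1L); dim(y) <- dim(x) }
  w <- oddWindow(windowSize, dim(x)[1])
  g <- gaussianWindow(w, sigma)
  C1 <- (k1 * 1)^2; C2 <- (k2 * 1)^2
  mean(vapply(seq_len(dim(x)[3]), function(ch)
    mean(ssimMaps(x[, , ch], y[, , ch], g, C1, C2)$ssim), numeric(1)))
}

#' Multi-scale structural similarity (MS-SSIM)
#'
#' The contrast-structure term is evaluated at each scale (each scale halves
#' the resolution by 2x2 average pooling), the full SSIM (with luminance) at
#' the coarsest scale, and the per-scale means are combined as a weighted
#' geometric product. With a single weight the measure reduces exactly to
#' [ssim()]. Scales that would shrink the image below 8 pixels are dropped
#' and the remaining weights renormalized to sum to 1.
#'
#' @inheritParams ssim
#' @param weights per-scale exponents; the default is the standard 5-scale
#'   parameterization (0.0448, 0.2856, 0.3001, 0.2363, 0.1333).
#' @return a scalar in [0, 1] (non-negative luminance convention: per-scale
#'   means are floored at 0 before the geometric combination).
#' @export
msSsim <- function(x, y, weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333),
                   windowSize = 11L, k1 = 0.01, k2 = 0.03, sigma = 1.5) {
  if (!identical(dim(x), dim(y)))
    stop("invalid argument: images must have identical dimensions")
  if (length(dim(x)) == 2L) { dim(x) <- c(dim(x), 1L); dim(y) <- dim(x) }
  size <- dim(x)[1]
  maxScales <- 1L
  while (maxScales < length(weights) && size %/% 2^maxScales >= 8L)
    maxScales <- maxScales + 1L
  if (maxScales < 1L)
    stop("invalid argument: image too small for any scale")
  M <- min(length(weights), maxScales)
  wts <- weights[seq_len(M)] / sum(weights[seq_len(M)])
  C1 <- (k1 * 1)^2; C2 <- (k2 * 1)^2
  val <- 1
  for (s in seq_len(M)) {
    w <- oddWindow(windowSize, dim(x)[1])
    g <- gaussianWindow(w, sigma)
    csMean <- 0; ssimMean <- 0
    for (ch in seq_len(dim(x)[3])) {
      maps <- ssimMaps(x[, , ch], y[, , ch], g, C1, C2)
      csMean <- csMean + mean(maps$cs) / dim(x)[3]
      ssimMean <- ssimMean + mean(maps$ssim) / dim(x)[3]
    }
    ## negative means are floored before fractional exponents (the
    ## non-negative convention); an integer exponent needs no floor, which
    ## keeps the single-scale case exactly equal to SSIM
    pw <- function(base, w) {
      if (base < 0 && abs(w - round(w)) > 1e-12) base <- 0
      base^w
    }
    if (s < M) {
      val <- val * pw(csMean, wts[s])
      x <- avgPool2(x); y <- avgPool2(y)
    } else {
      val <- val * pw(ssimMean, wts[s])
    }
  }
  val
}

## 2x2 average pooling of an H x W x C array (odd trailing row/col dropped).
avgPool2 <- function(x) {
  d <- dim(x)
  h <- d[1] %/% 2L; w <- d[2] %/% 2L
  out <- array(0, c(h, w, d[3]))
  for (a in 1:2) for (b in 1:2)
    out <- out + x[seq(a, by = 2L, length.out = h),
                   seq(b, by = 2L, length.out = w), , drop = FALSE]
  out / 4
}

#' Evaluate generated tiles against their conditioning sources
#'
#' Computes SSIM, MS-SSIM and the perceptual (LPIPS-style) distance for each
#' generated/reference pair and averages them. Under `"by-source"` pairing,
#' `generated[i]` was conditioned on the latent/cluster of `references[i]`,
#' so the two datasets must have equal length.
#'
#' @param generated,references [TileSet-class] objects.
#' @param pairing pairing strategy; only `"by-source"` is defined.
#' @param extractor feature extractor for the perceptual distance.
#' @param k optional cluster-set size recorded in the report.
#' @return a one-row `data.frame` with columns `k`, `ssim`, `ms_ssim`,
#'   `lpips`, `n_pairs`.
#' @export
evaluateGeneration <- function(generated, references, pairing = "by-source",
                               extractor = randomFeatureExtractor(),
                               k = NA_integer_) {
  pairing <- match.arg(pairing, "by-source")
  if (length(generated) != length(references))
    stop("invalid argument: by-source pairing needs equal dataset sizes")
  n <- length(generated)
  vals <- vapply(seq_len(n), function(i) {
    gx <- tiles(generated)[[i]]
    rx <- tiles(references)[[i]]
    c(ssim(gx, rx), msSsim(gx, rx), perceptualDistance(gx, rx, extractor))
  }, numeric(3))
  data.frame(k = k, ssim = mean(vals[1, ]), ms_ssim = mean(vals[2, ]),
             lpips = mean(vals[3, ]), n_pairs = n)
}

#' Select the best cluster-set size from generation-quality reports
#'
#' Each metric votes for one k (maximize SSIM and MS-SSIM, minimize the
#' perceptual distance); the k winning the majority of the three votes is
#' returned, with ties broken toward the smallest tied k.
#'
#' @param reports `data.frame` with one row per cluster-set size and columns
#'   `k`, `ssim`, `ms_ssim`, `lpips` (as produced by [evaluateGeneration()]).
#' @return a list with `k` (winning size), `winners` (per-metric winning k)
#'   and `votes`.
#' @export
selectBestClusterSet <- function(reports) {
  selectByVotes(reports, c(ssim = 1, ms_ssim = 1, lpips = -1))
}
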