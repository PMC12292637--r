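## Frozen feature extractors for perceptual distances.
##
## The perceptual (LPIPS-style) distance compares deep feature maps of two
## images. The packaged default extractor is a frozen convolutional stack
## with fixed-seed random weights: random convolutional features preserve
## the structure of the metric (multi-layer, multi-channel, spatially
## resolved) without requiring any pretrained weights. A custom extractor
## can be supplied as long as it follows the same contract.

#' Create a frozen random convolutional feature extractor
#'
#' A small stack of strided convolutions with SiLU activations and
#' fixed-seed random weights. Feature maps are tapped after each activation.
#' Applying the extractor twice to the same image yields identical features
#' (frozen contract).
#'
#' @param seed RNG seed fixing the weights.
#' @param channels integer vector, output channels of each tapped stage.
#' @param inputChannels number of image channels (3 for RGB).
#' @return an object of class `"FeatureExtractor"` with fields `layers`
#'   (named list of `(name, channels)` descriptors), `apply` (function
#'   mapping an `H x W x C` image to a list of feature maps) and
#'   `frozen = TRUE`.
#' @export
randomFeatureExtractor <- function(seed = 11L, channels = c(8L, 16L),
                                   inputChannels = 3L) {
  stacks <- withr::with_seed(as.integer(seed), {
    cin <- inputChannels
    lapply(channels, function(cout) {
      ly <- list(makeConv(3L, cin, cout, stride = 2L, pad = 1L),
                 list(type = "silu"))
      cin <<- cout
      ly
    })
  })
  ex <- list(
    kind = "conv",
    stacks = stacks,
    layers = lapply(seq_along(channels), function(i)
      list(name = sprintf("stage%d", i), channels = channels[i])),
    inputChannels = inputChannels,
    frozen = TRUE
  )
  ex$apply <- function(image) extractorFeatures(ex, image)
  class(ex) <- "FeatureExtractor"
  ex
}

#' Wrap a custom feature function as an extractor
#'
#' Mostly useful for testing the perceptual-distance computation against
#' hand-evaluated cases (e.g. an identity extractor whose single "feature
#' map" is the image itself).
#'
#' @param applyFn function mapping an `H x W x C` image to a list of
#'   `h x w x c` feature arrays.
#' @param layers list of `(name, channels)` descriptors.
#' @return a `"FeatureExtractor"` object.
#' @export
customFeatureExtractor <- function(applyFn, layers) {
  ex <- list(kind = "custom", apply = applyFn, layers = layers, frozen = TRUE)
  class(ex) <- "FeatureExtractor"
  ex
}

#' @export
print.FeatureExtractor <- function(x, ...) {
  cat(sprintf("FeatureExtractor (%s), %d tapped layer(s): %s\n", x$kind,
              length(x$layers),
              paste(vapply(x$layers, function(l)
                sprintf("%s[%d]", l$name, l$channels), character(1)),
                collapse = ", ")))
  invisible(x)
}

## Internal: run the conv stack on one image, returning tapped feature maps
## (and caches when gradients are needed).
extractorForward <- function(ex, image, keepCaches = FALSE) {
  x <- array(image, c(dim(image)[1:2], dim(image)[3], 1L))
  feats <- vector("list", length(ex$stacks))
  caches <- vector("list", length(ex$stacks))
  for (i in seq_along(ex$stacks)) {
    r <- seqForward(x, ex$stacks[[i]])
    feats[[i]] <- r$out[, , , 1L, drop = TRUE]
    if (length(dim(r$out)) == 4L && dim(r$out)[3] == 1L)
      dim(feats[[i]]) <- dim(r$out)[1:3]
    if (keepCaches) caches[[i]] <- r$caches
    x <- r$out
  }
  list(features = feats, caches = caches)
}

extractorFeatures <- function(ex, image) {
  if (!is.null(ex$stacks)) extractorForward(ex, image)$features
  else ex$apply(image)
}

## Internal: per-layer LPIPS-style term. Feature vectors are unit-normalized
## across channels at every spatial position, squared differences are
## weighted per channel (non-negative weights) and averaged spatially.
## Returns the scalar term plus (optionally) the gradient w.r.t. fy.
.lpipsEps <- 1e-10

lpipsLayerTerm <- function(fx, fy, w = NULL, wantGrad = FALSE) {
  if (length(dim(fx)) == 2L) dim(fx) <- c(dim(fx), 1L)
  if (length(dim(fy)) == 2L) dim(fy) <- c(dim(fy), 1L)
  d <- dim(fx)
  if (is.null(w)) w <- rep(1, d[3])
  if (any(w < 0)) stop("perceptual channel weights must be non-negative")
  if (any(!is.finite(fx)) || any(!is.finite(fy)))
    stop("numeric error: extractor emitted non-finite features")
  nx <- sqrt(apply(fx^2, c(1, 2), sum)) + .lpipsEps
  ny <- sqrt(apply(fy^2, c(1, 2), sum)) + .lpipsEps
  ux <- fx / as.vector(nx)
  uy <- fy / as.vector(ny)
  diff2 <- (ux - uy)^2
  wArr <- array(rep(w, each = d[1] * d[2]), d)
  val <- sum(wArr * diff2) / (d[1] * d[2])
  if (!wantGrad) return(list(value = val))
  gU <- -2 * wArr * (ux - uy) / (d[1] * d[2])     # dval/duy
  dotGU <- apply(gU * uy, c(1, 2), sum)           # per-position <g, uy>
  gF <- (gU - uy * as.vector(dotGU)) / as.vector(ny)
  list(value = val, dfy = gF)
}

#' Perceptual (LPIPS-style) distance between two images
#'
#' Feature maps of both images are extracted at each tapped layer of a
#' frozen network; at every spatial position the channel vector is
#' normalized to unit length; squared differences are weighted by
#' non-negative per-channel weights, averaged over the spatial dimensions,
#' and summed across layers. Symmetric in its two image arguments, zero for
#' identical inputs.
#'
#' @param x,y `H x W x C` numeric arrays in [0, 1], same shape.
#' @param extractor a [randomFeatureExtractor()] /
#'   [customFeatureExtractor()] object.
#' @param weights optional list of per-layer non-negative channel-weight
#'   vectors (default: all ones).
#' @return a non-negative scalar.
#' @export
perceptualDistance <- function(x, y, extractor = randomFeatureExtractor(),
                               weights = NULL) {
  if (!identical(dim(x), dim(y)))
    stop("invalid argument: images must have identical dimensions")
  fx <- extractorFeatures(extractor, x)
  fy <- extractorFeatures(extractor, y)
  tot <- 0
  for (i in seq_along(fx)) {
    w <- if (is.null(weights)) NULL else weights[[i]]
    tot <- tot + lpipsLayerTerm(fx[[i]], fy[[i]], w)$value
  }
  tot
}

#' @rdname perceptualDistance
#' @export
lpipsMetric <- function(x, y, extractor = randomFeatureExtractor(),
                        weights = NULL) {
  perceptualDistance(x, y, extractor, weights)
}

## Internal: perceptual distance plus its gradient w.r.t. the second image
## (the reconstruction), for use as a training loss. Conv extractors only.
perceptualGrad <- function(x, y, extractor, weights = NULL) {
  if (is.null(extractor$stacks))
    stop("gradients are only available for conv-stack extractors")
  fx <- extractorForward(extractor, x)$features
  fyr <- extractorForward(extractor, y, keepCaches = TRUE)
  tot <- 0
  dy <- array(0, c(dim(y)[1:2], dim(y)[3], 1L))
  ## backprop each tapped stage; stage i consumes the output of stage i-1,
  ## so gradients are chained from the deepest tap back to the image
  dUpstream <- NULL
  for (i in rev(seq_along(fyr$features))) {
    w <- if (is.null(weights)) NULL else weights[[i]]
    term <- lpipsLayerTerm(fx[[i]], fyr$features[[i]], w, wantGrad = TRUE)
    tot <- tot + term$value
    g <- term$dfy
    dim(g) <- c(dim(g), 1L)
    if (!is.null(dUpstream)) g <- g + dUpstream
    dUpstream <- seqBackward(g, extractor$stacks[[i]], fyr$caches[[i]])$dx
  }
  dy <- dUpstream
  list(value = tot, dy = dy[, , , 1L, drop = TRUE])
}
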