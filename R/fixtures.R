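## Synthetic H&E-like tile generator.
##
## Real tiles from the motivating histopathology setting are not distributed
## with the package, so every downstream stage (autoencoder, clustering,
## diffusion, evaluation) is exercised on procedurally generated tiles with
## known phenotype classes. The generator renders: a near-white background,
## void regions (smooth thresholded noise), an eosin-tinted stromal band-pass
## texture, optional red-blood-cell regions, and nuclei placed as a
## homogeneous spatial Poisson process rendered as hematoxylin-hued discs.

.BG_COLOR <- c(0.96, 0.95, 0.96)

#' Define a synthetic tile phenotype
#'
#' A phenotype parameterizes one class of synthetic H&E tiles. The axes mirror
#' the qualitative features a pathologist uses to describe tumor tiles: nuclear
#' density, voids/empty space, stromal texture, and red-blood-cell content.
#'
#' @param nucleusDensity expected nuclei per pixel^2 of tissue (> 0).
#' @param nucleusRadius nucleus disc radius in pixels (> 0).
#' @param voidFraction fraction of the tile that is background void, in [0, 1].
#' @param stromaIntensity strength of the eosin stromal texture, in [0, 1].
#' @param rbcFraction fraction of tissue recolored as red blood cells, [0, 1].
#' @param hematoxylinHue,eosinHue,rbcHue RGB triples in [0, 1].
#' @param name optional phenotype name.
#' @return a list of class `"SyntheticPhenotype"`.
#' @export
makePhenotype <- function(nucleusDensity = 0.01, nucleusRadius = 1.5,
                          voidFraction = 0, stromaIntensity = 0.5,
                          rbcFraction = 0,
                          hematoxylinHue = c(0.36, 0.21, 0.52),
                          eosinHue = c(0.91, 0.56, 0.68),
                          rbcHue = c(0.72, 0.12, 0.15),
                          name = "phenotype") {
  fr <- c(voidFraction = voidFraction, stromaIntensity = stromaIntensity,
          rbcFraction = rbcFraction)
  if (any(fr < 0) || any(fr > 1))
    stop("invalid argument: ", paste(names(fr)[fr < 0 | fr > 1], collapse = ", "),
         " must lie in [0, 1]")
  if (nucleusDensity <= 0 || nucleusRadius <= 0)
    stop("invalid argument: nucleusDensity and nucleusRadius must be > 0")
  for (hue in list(hematoxylinHue, eosinHue, rbcHue))
    if (length(hue) != 3L || any(hue < 0) || any(hue > 1))
      stop("invalid argument: hues must be RGB triples in [0, 1]")
  structure(list(nucleusDensity = nucleusDensity,
                 nucleusRadius = nucleusRadius,
                 voidFraction = voidFraction,
                 stromaIntensity = stromaIntensity,
                 rbcFraction = rbcFraction,
                 hematoxylinHue = hematoxylinHue,
                 eosinHue = eosinHue, rbcHue = rbcHue, name = name),
            class = "SyntheticPhenotype")
}

#' Built-in bank of 14 synthetic phenotypes
#'
#' Fourteen presets spanning the qualitative tile types seen in H&E tumor
#' sections: dense and sparse cellular tissue, stroma-rich regions, tiles with
#' small/large voids, red-blood-cell areas, tissue/empty-space boundaries, and
#' near-empty tiles. Every pair of presets differs in at least one parameter,
#' so classes are separable by construction.
#'
#' @return a named list of 14 [makePhenotype()] objects.
#' @export
phenotypeBank <- function() {
  list(
    dense_tumor    = makePhenotype(0.030, 1.8, 0.00, 0.55, 0,    name = "dense_tumor"),
    sparse_tissue  = makePhenotype(0.004, 1.8, 0.05, 0.45, 0,    name = "sparse_tissue"),
    liver_rbc      = makePhenotype(0.010, 1.6, 0.00, 0.50, 0.35, name = "liver_rbc"),
    large_voids    = makePhenotype(0.012, 1.6, 0.50, 0.50, 0,    name = "large_voids"),
    tumor_voids    = makePhenotype(0.025, 1.8, 0.30, 0.55, 0,    name = "tumor_voids"),
    stroma_rich    = makePhenotype(0.008, 1.5, 0.00, 0.95, 0,    name = "stroma_rich"),
    empty_space    = makePhenotype(0.001, 1.5, 0.97, 0.20, 0,    name = "empty_space"),
    dense_tissue   = makePhenotype(0.028, 1.3, 0.05, 0.40, 0,    name = "dense_tissue"),
    small_voids    = makePhenotype(0.012, 1.6, 0.18, 0.50, 0,    name = "small_voids"),
    rbc_boundary   = makePhenotype(0.008, 1.6, 0.45, 0.45, 0.30, name = "rbc_boundary"),
    tissue_voids   = makePhenotype(0.015, 1.6, 0.35, 0.50, 0,    name = "tissue_voids"),
    tissue_edge    = makePhenotype(0.010, 1.6, 0.55, 0.50, 0,    name = "tissue_edge"),
    normal_liver   = makePhenotype(0.007, 1.4, 0.00, 0.70, 0.05, name = "normal_liver"),
    liver_edge     = makePhenotype(0.006, 1.4, 0.65, 0.60, 0.08, name = "liver_edge")
  )
}

## Internal: smooth random field in [0, 1] via two passes of a separable box
## blur over uniform noise. `r` is the blur radius in pixels.
smoothField <- function(size, r = max(2L, size %/% 8L)) {
  m <- matrix(stats::runif(size * size), size, size)
  for (pass in 1:2) {
    m <- boxBlur1d(m, r)        # rows
    m <- t(boxBlur1d(t(m), r))  # columns
  }
  rng <- range(m)
  if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0 + 0.5
}

boxBlur1d <- function(m, r) {
  n <- ncol(m)
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  lo <- pmax(seq_len(n) - r - 1L, 0L)
  hi <- pmin(seq_len(n) + r, n)
  (cs[, hi + 1L, drop = FALSE] - cs[, lo + 1L, drop = FALSE]) /
    rep(hi - lo, each = nrow(m))
}

#' Render one synthetic H&E tile
#'
#' Deterministic for a fixed (phenotype, size, seed). The number of rendered
#' nuclei is drawn from a Poisson law with mean
#' `nucleusDensity * (1 - voidFraction) * size^2` and is attached to the
#' result as attribute `"nucleusCount"`.
#'
#' @param phenotype a [makePhenotype()] object.
#' @param size tile side length in pixels (>= 8; study scale 128, test scale 32).
#' @param seed integer RNG seed.
#' @return a `size x size x 3` numeric array in [0, 1].
#' @export
#' @examples
#' tile <- generateTile(phenotypeBank()$dense_tumor, size = 32, seed = 1)
#' range(tile)
generateTile <- function(phenotype, size, seed = 1L) {
  if (!inherits(phenotype, "SyntheticPhenotype"))
    phenotype <- do.call(makePhenotype, phenotype)
  if (size < 8L) stop("invalid argument: size must be >= 8")
  p <- phenotype
  withr::with_seed(as.integer(seed), {
    img <- array(rep(.BG_COLOR, each = size * size), dim = c(size, size, 3))
    nNuc <- 0L
    if (p$voidFraction < 1) {
      ## void mask: smooth field thresholded so exactly voidFraction of
      ## pixels are background
      tissue <- matrix(TRUE, size, size)
      if (p$voidFraction > 0) {
        f <- smoothField(size)
        thr <- stats::quantile(f, p$voidFraction)
        tissue <- f > thr
        if (!any(tissue)) tissue[which.max(f)] <- TRUE
      }
      ## stromal eosin texture: band-pass of smooth noise, always tinting
      ## tissue when stromaIntensity > 0
      texF <- smoothField(size, r = max(1L, size %/% 16L))
      texC <- smoothField(size, r = max(2L, size %/% 6L))
      tex <- texF - texC
      rngT <- range(tex)
      tex <- if (rngT[2] > rngT[1]) (tex - rngT[1]) / (rngT[2] - rngT[1]) else tex * 0
      alpha <- p$stromaIntensity * (0.35 + 0.65 * tex)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[tissue] <- (1 - alpha[tissue]) * .BG_COLOR[ch] +
          alpha[tissue] * p$eosinHue[ch]
        img[, , ch] <- plane
      }
      ## red-blood-cell regions: recolor a fraction of tissue area
      if (p$rbcFraction > 0) {
        g <- smoothField(size, r = max(1L, size %/% 10L))
        gv <- g[tissue]
        thr <- stats::quantile(gv, 1 - p$rbcFraction)
        rbc <- tissue & (g > thr)
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[rbc] <- 0.25 * plane[rbc] + 0.75 * p$rbcHue[ch]
          img[, , ch] <- plane
        }
      }
      ## nuclei: homogeneous Poisson process on the tissue region
      lambda <- p$nucleusDensity * (1 - p$voidFraction) * size^2
      nNuc <- stats::rpois(1L, lambda)
      if (nNuc > 0L) {
        tIdx <- which(tissue, arr.ind = TRUE)
        pick <- tIdx[sample.int(nrow(tIdx), nNuc, replace = TRUE), , drop = FALSE]
        jit <- matrix(stats::runif(2L * nNuc, -0.5, 0.5), ncol = 2)
        rad <- p$nucleusRadius
        w <- ceiling(rad)
        for (k in seq_len(nNuc)) {
          cy <- pick[k, 1] + jit[k, 1]
          cx <- pick[k, 2] + jit[k, 2]
          ys <- max(1L, floor(cy - w)):min(size, ceiling(cy + w))
          xs <- max(1L, floor(cx - w)):min(size, ceiling(cx + w))
          dd <- outer((ys - cy)^2, (xs - cx)^2, "+")
          hit <- dd <= rad^2
          if (!any(hit)) next
          for (ch in 1:3) {
            sub <- img[ys, xs, ch, drop = FALSE]
            sub[hit] <- 0.15 * sub[hit] + 0.85 * p$hematoxylinHue[ch]
            img[ys, xs, ch] <- sub
          }
        }
      }
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    attr(img, "nucleusCount") <- nNuc
    img
  })
}

#' Generate a class-balanced synthetic tile dataset
#'
#' Draws `nClasses` phenotypes from a preset bank (or a user-supplied list)
#' and renders `nPerClass` tiles per class. Labels are the 0-based class
#' indices, ordered in contiguous blocks (`0,...,0,1,...,1,...`).
#'
#' @param nClasses number of phenotype classes (>= 2).
#' @param nPerClass tiles per class (>= 1).
#' @param size tile side length in pixels.
#' @param seed master RNG seed; per-tile seeds are derived deterministically.
#' @param phenotypes list of phenotypes to draw classes from (defaults to
#'   [phenotypeBank()]).
#' @param split dataset split tag.
#' @return a [TileSet-class] with ground-truth labels.
#' @export
generateTileSet <- function(nClasses, nPerClass, size = 32L, seed = 1L,
                            phenotypes = phenotypeBank(), split = "train") {
  if (nClasses < 2L) stop("invalid argument: nClasses must be >= 2")
  if (nPerClass < 1L) stop("invalid argument: nPerClass must be >= 1")
  if (nClasses > length(phenotypes))
    stop("invalid argument: nClasses exceeds the ", length(phenotypes),
         " available phenotypes; supply a larger 'phenotypes' list")
  n <- nClasses * nPerClass
  tileSeeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max - 1L, n))
  tilesList <- vector("list", n)
  labels <- integer(n)
  idx <- 0L
  for (cl in seq_len(nClasses)) {
    for (r in seq_len(nPerClass)) {
      idx <- idx + 1L
      tl <- generateTile(phenotypes[[cl]], size, tileSeeds[idx])
      attr(tl, "nucleusCount") <- NULL
      tilesList[[idx]] <- tl
      labels[idx] <- cl - 1L
    }
  }
  TileSet(tilesList,
          ids = sprintf("%s_c%02d_%04d", split, rep(seq_len(nClasses) - 1L,
                                                    each = nPerClass),
                        sequence(rep(nPerClass, nClasses)) - 1L),
          labels = labels, split = split)
}
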