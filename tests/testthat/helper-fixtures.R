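# Shared test fixtures, all generated in code.

# a small labeled tile set (3 phenotype classes)
tinyTileSet <- function(nPerClass = 2L, size = 16L, seed = 42L) {
  generateTileSet(3L, nPerClass, size = size, seed = seed)
}

# random valid tile
randomTile <- function(size = 16L, seed = 1L) {
  withr::with_seed(seed, array(runif(size * size * 3), c(size, size, 3)))
}

# random labeled point set with every cluster non-empty
randomPointSet <- function(n, p, k, seed) {
  withr::with_seed(seed, {
    labels <- c(seq_len(k) - 1L, sample.int(k, n - k, replace = TRUE) - 1L)
    list(points = matrix(rnorm(n * p), n, p), labels = labels)
  })
}

# random soft assignment (rows on the simplex)
randomAssignment <- function(n, K, seed) {
  withr::with_seed(seed, {
    m <- matrix(rexp(n * K), n, K)
    m / rowSums(m)
  })
}

# --- independent brute-force validity indices (loop-based oracles) ---

bfPairs <- function(points, labels) {
  n <- nrow(points)
  intra <- c(); inter <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((points[i, ] - points[j, ])^2))
    if (labels[i] == labels[j]) intra <- c(intra, d) else inter <- c(inter, d)
  }
  list(intra = intra, inter = inter)
}

bfScatter <- function(points, labels) {
  grand <- colMeans(points)
  ssw <- 0; ssb <- 0
  for (cl in unique(labels)) {
    rows <- points[labels == cl, , drop = FALSE]
    cen <- colMeans(rows)
    for (i in seq_len(nrow(rows))) ssw <- ssw + sum((rows[i, ] - cen)^2)
    ssb <- ssb + nrow(rows) * sum((cen - grand)^2)
  }
  list(ssw = ssw, ssb = ssb)
}

bfCalinskiHarabasz <- function(points, labels) {
  s <- bfScatter(points, labels)
  k <- length(unique(labels)); n <- nrow(points)
  (s$ssb / s$ssw) * (n - k) / (k - 1)
}

bfCIndex <- function(points, labels) {
  pr <- bfPairs(points, labels)
  all <- sort(c(pr$intra, pr$inter))
  nw <- length(pr$intra)
  s <- sum(pr$intra)
  (s - sum(all[1:nw])) / (sum(rev(all)[1:nw]) - sum(all[1:nw]))
}

bfDunn <- function(points, labels) {
  pr <- bfPairs(points, labels)
  min(pr$inter) / max(pr$intra)
}

bfHartigan <- function(points, labels) {
  s <- bfScatter(points, labels)
  log(s$ssb / s$ssw)
}

bfMcclainRao <- function(points, labels) {
  pr <- bfPairs(points, labels)
  mean(pr$intra) / mean(pr$inter)
}
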