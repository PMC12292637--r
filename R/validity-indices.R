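#' @include AllClasses.R
NULL

## Internal: validate a labeled point set and return a canonical form.
## Cluster IDs are used as given (any integer coding); every cluster must be
## non-empty and n > k so the Calinski-Harabasz (n - k) factor is positive.
checkLabeledPointSet <- function(points, labels) {
  points <- as.matrix(points)
  if (!is.numeric(points) || anyNA(points) || any(!is.finite(points)))
    stop("'points' must be a finite numeric matrix")
  labels <- as.integer(labels)
  if (length(labels) != nrow(points))
    stop("'labels' must have one entry per row of 'points'")
  ids <- sort(unique(labels))
  k <- length(ids)
  if (k < 2L)
    stop("need at least 2 clusters")
  if (nrow(points) <= k)
    stop("need more points than clusters (n > k)")
  list(points = points, labels = labels, ids = ids, k = k, n = nrow(points))
}

## Internal: within- and between-cluster sums of squares about the centroids.
scatterSums <- function(ps) {
  grand <- colMeans(ps$points)
  ssw <- 0
  ssb <- 0
  for (id in ps$ids) {
    rows <- ps$points[ps$labels == id, , drop = FALSE]
    cen <- colMeans(rows)
    ssw <- ssw + sum(sweep(rows, 2, cen)^2)
    ssb <- ssb + nrow(rows) * sum((cen - grand)^2)
  }
  list(ssw = ssw, ssb = ssb)
}

#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster dispersion, scaled by the
#' degrees of freedom: \eqn{CH = \frac{tr(B_k)}{tr(W_k)} \times
#' \frac{n-k}{k-1}}, where \eqn{B_k} weights squared centroid-to-grand-centroid
#' distances by cluster size and \eqn{W_k} sums squared distances of points to
#' their cluster centroid. Larger is better.
#'
#' @param points numeric matrix, one row per observation.
#' @param labels integer cluster assignment per row (any coding; every cluster
#'   must be non-empty).
#' @return a single numeric value.
#' @seealso [consensusSelectK()] for direction-aware model selection over
#'   several cluster counts.
#' @export
#' @examples
#' x <- matrix(c(0, 1, 10, 11), ncol = 1)
#' calinskiHarabasz(x, c(0, 0, 1, 1))  # 200
calinskiHarabasz <- function(points, labels) {
  ps <- checkLabeledPointSet(points, labels)
  s <- scatterSums(ps)
  if (s$ssw <= 0)
    stop("degenerate input: within-cluster scatter is zero")
  (s$ssb / s$ssw) * (ps$n - ps$k) / (ps$k - 1)
}

#' C index (Hubert-Levin)
#'
#' Compares the sum S of intra-cluster pairwise Euclidean distances with the
#' best and worst values attainable with the same number of intra-cluster
#' pairs: S_min / S_max are the sums of the n_w smallest / largest distances
#' among all pairwise distances in the data set (global pool). Returns
#' \eqn{(S - S_{min}) / (S_{max} - S_{min})}, in [0, 1]; smaller is better.
#'
#' @inheritParams calinskiHarabasz
#' @return a single numeric value in [0, 1].
#' @export
cIndex <- function(points, labels) {
  ps <- checkLabeledPointSet(points, labels)
  d <- stats::dist(ps$points)
  same <- stats::dist(matrix(ps$labels, ncol = 1)) == 0
  nw <- sum(same)
  if (nw < 1L)
    stop("degenerate input: no intra-cluster pair exists")
  s <- sum(d[same])
  ds <- sort(d)
  smin <- sum(ds[seq_len(nw)])
  smax <- sum(ds[seq.int(length(ds) - nw + 1L, length(ds))])
  if (smax - smin <= 1e-12 * max(smax, 1))
    stop("degenerate input: all pairwise distances are equal")
  (s - smin) / (smax - smin)
}

#' Dunn index
#'
#' Minimum single-linkage distance between any two clusters divided by the
#' maximum cluster diameter (largest intra-cluster point-to-point distance).
#' Larger is better.
#'
#' @inheritParams calinskiHarabasz
#' @return a single numeric value (>= 0).
#' @export
dunnIndex <- function(points, labels) {
  ps <- checkLabeledPointSet(points, labels)
  dm <- as.matrix(stats::dist(ps$points))
  inter <- Inf
  diam <- 0
  for (i in seq_len(ps$k)) {
    ri <- ps$labels == ps$ids[i]
    diam <- max(diam, max(dm[ri, ri]))
    for (j in seq_len(ps$k)) {
      if (j <= i) next
      rj <- ps$labels == ps$ids[j]
      inter <- min(inter, min(dm[ri, rj]))
    }
  }
  if (diam <= 0)
    stop("degenerate input: maximum cluster diameter is zero")
  inter / diam
}

#' Hartigan index
#'
#' Natural logarithm of the ratio of the between-cluster sum of squares to the
#' within-cluster sum of squares, \eqn{H = \ln(SSB / SSW)}. Larger is better.
#'
#' @inheritParams calinskiHarabasz
#' @return a single numeric value.
#' @export
hartiganIndex <- function(points, labels) {
  ps <- checkLabeledPointSet(points, labels)
  s <- scatterSums(ps)
  if (s$ssw <= 0 || s$ssb <= 0)
    stop("degenerate input: SSB and SSW must both be positive")
  log(s$ssb / s$ssw)
}

#' McClain-Rao index
#'
#' Ratio of the average intra-cluster pairwise distance to the average
#' inter-cluster pairwise distance. Smaller is better.
#'
#' @inheritParams calinskiHarabasz
#' @return a single numeric value (>= 0).
#' @export
mcclainRao <- function(points, labels) {
  ps <- checkLabeledPointSet(points, labels)
  d <- stats::dist(ps$points)
  same <- stats::dist(matrix(ps$labels, ncol = 1)) == 0
  nw <- sum(same)
  nb <- sum(!same)
  if (nw < 1L || nb < 1L)
    stop("degenerate input: need at least one intra- and one inter-cluster pair")
  interMean <- sum(d[!same]) / nb
  if (interMean <= 0)
    stop("degenerate input: inter-cluster mean distance is zero")
  (sum(d[same]) / nw) / interMean
}

#' All five internal validity indices for one clustering
#'
#' @inheritParams calinskiHarabasz
#' @return a one-row `data.frame` with columns `k`, `ch`, `c_index`, `dunn`,
#'   `hartigan`, `mcclain_rao`.
#' @export
validityIndexReport <- function(points, labels) {
  ps <- checkLabeledPointSet(points, labels)
  data.frame(
    k = ps$k,
    ch = calinskiHarabasz(points, labels),
    c_index = cIndex(points, labels),
    dunn = dunnIndex(points, labels),
    hartigan = hartiganIndex(points, labels),
    mcclain_rao = mcclainRao(points, labels)
  )
}

#' Direction-aware consensus selection of the cluster count
#'
#' Each index votes for one candidate k: the Calinski-Harabasz, Dunn and
#' Hartigan indices vote for the k that maximizes them, the C and McClain-Rao
#' indices for the k that minimizes them. The k winning the majority of the
#' five votes is selected; ties are broken toward the smallest tied k.
#'
#' @param reports a `data.frame` with one row per candidate k and columns
#'   `k`, `ch`, `c_index`, `dunn`, `hartigan`, `mcclain_rao` (as produced by
#'   [validityIndexReport()]).
#' @return a list with elements `k` (the selected count), `winners` (named
#'   numeric vector, the winning k per index) and `votes` (vote count per
#'   candidate k).
#' @export
#' @examples
#' r2 <- validityIndexReport(matrix(rnorm(40), 20), rep(0:1, 10))
#' r4 <- validityIndexReport(matrix(rnorm(40), 20), rep(0:3, 5))
#' consensusSelectK(rbind(r2, r4))
consensusSelectK <- function(reports) {
  directions <- c(ch = 1, c_index = -1, dunn = 1, hartigan = 1, mcclain_rao = -1)
  selectByVotes(reports, directions)
}

## Internal: shared majority-vote machinery for index- and metric-based
## selection. `directions` is +1 (maximize) or -1 (minimize) per column.
selectByVotes <- function(reports, directions) {
  reports <- as.data.frame(reports)
  need <- c("k", names(directions))
  missing <- setdiff(need, colnames(reports))
  if (length(missing))
    stop("reports lack column(s): ", paste(missing, collapse = ", "))
  if (nrow(reports) < 2L)
    stop("need at least 2 reports")
  if (anyDuplicated(reports$k))
    stop("duplicate k values in reports")
  winners <- vapply(names(directions), function(col) {
    v <- reports[[col]] * directions[[col]]
    cand <- reports$k[v == max(v)]
    min(cand)  # within-index tie: smallest k
  }, numeric(1))
  votes <- table(winners)
  top <- as.numeric(names(votes)[votes == max(votes)])
  list(k = min(top), winners = winners,
       votes = stats::setNames(as.integer(votes), names(votes)))
}
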