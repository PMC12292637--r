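## Information-maximization clustering of latent features.
##
## A small feed-forward head (p -> hidden -> K, softmax) is trained by
## gradient ascent on the mutual information between inputs and cluster
## assignments: MI = H(marginal) - H(conditional), with the marginal entropy
## encouraging balanced clusters and the conditional entropy encouraging
## confident assignments. A self-augmented-training (SAT) consistency term
## penalizes the KL divergence from the (fixed) prediction on an input to
## the prediction on its transformed version; the hard argmax labels are the
## diffusion conditioning signal. Entropies use the natural log throughout,
## so 0 <= MI <= ln K.

#' Pool a quantized latent into a feature vector
#'
#' @param q a [QuantizedLatent-class] (or a plain `h x w x d` array).
#' @param mode `"mean-pool"` (spatial average of the embedded vectors,
#'   p = d) or `"flatten"` (p = h*w*d).
#' @return a numeric vector.
#' @export
latentFeatures <- function(q, mode = c("mean-pool", "flatten")) {
  mode <- match.arg(mode)
  z <- if (is(q, "QuantizedLatent")) latentEmbedded(q) else q
  if (length(dim(z)) != 3L) stop("invalid argument: expected an h x w x d grid")
  if (mode == "flatten") return(as.vector(z))
  apply(z, 3L, mean)
}

## Internal: entropy of a probability vector, natural log, 0*log0 = 0.
entropyNat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

checkSoftAssignment <- function(probs) {
  probs <- as.matrix(probs)
  if (any(probs < -1e-9))
    stop("invalid argument: assignment probabilities must be non-negative")
  if (max(abs(rowSums(probs) - 1)) > 1e-6)
    stop("invalid argument: assignment rows must sum to 1")
  probs
}

#' Mutual-information objective of a soft assignment
#'
#' For an n x K matrix of cluster probabilities, reports the marginal
#' entropy H(Y) (entropy of the column means), the conditional entropy
#' H(Y|X) (mean row entropy) and their difference, the mutual information.
#'
#' @param probs n x K matrix; every row non-negative, summing to 1.
#' @return a list with `hMarginal`, `hConditional`, `mutualInfo`.
#' @export
#' @examples
#' miObjective(matrix(c(1, 0, 1, 0, 0, 1, 0, 1), 4, 2, byrow = TRUE))
miObjective <- function(probs) {
  probs <- checkSoftAssignment(probs)
  hMarg <- entropyNat(colMeans(probs))
  hCond <- mean(apply(probs, 1L, entropyNat))
  list(hMarginal = hMarg, hConditional = hCond,
       mutualInfo = hMarg - hCond)
}

#' Self-augmented-training consistency loss
#'
#' Mean KL divergence from the prediction on each original input (treated
#' as a fixed target) to the prediction on its augmented counterpart;
#' zero iff the paired predictions are identical.
#'
#' @param probs,probsAug n x K soft assignments for the originals and their
#'   positionally paired augmented versions.
#' @return a non-negative scalar.
#' @export
satLoss <- function(probs, probsAug) {
  probs <- checkSoftAssignment(probs)
  probsAug <- checkSoftAssignment(probsAug)
  if (!identical(dim(probs), dim(probsAug)))
    stop("invalid argument: paired assignments must have identical shape")
  eps <- 1e-12
  mean(rowSums(probs * (log(probs + eps) - log(probsAug + eps))))
}

#' Hard labels from a soft assignment
#'
#' Row-wise argmax with ties broken toward the lowest index; labels are
#' 0-based cluster IDs (the conditioning convention).
#'
#' @param probs n x K soft assignment.
#' @return integer vector of labels in [0, K).
#' @export
hardLabels <- function(probs) {
  probs <- checkSoftAssignment(probs)
  as.integer(max.col(probs, ties.method = "first") - 1L)
}

## ---- the clustering head ----

#' Initialize a clustering head
#'
#' A single-hidden-layer network (width `hidden`, SiLU activation) with a
#' K-way softmax output.
#'
#' @param p input feature dimension.
#' @param K number of clusters.
#' @param hidden hidden width.
#' @param seed RNG seed for initialization.
#' @return a list of class `"ClusterHead"`.
#' @export
clusterHead <- function(p, K, hidden = 64L, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    structure(list(
      W1 = matrix(stats::rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden),
      b1 = numeric(hidden),
      ## near-zero output layer: initial assignments start near-uniform so
      ## the marginal-entropy term can shape balanced clusters before the
      ## confidence term locks assignments in
      W2 = matrix(stats::rnorm(hidden * K, sd = 0.01), hidden, K),
      b2 = numeric(K),
      center = numeric(p), scale = rep(1, p),
      p = as.integer(p), K = as.integer(K), hidden = as.integer(hidden)
    ), class = "ClusterHead")
  })
}

#' @export
print.ClusterHead <- function(x, ...) {
  cat(sprintf("ClusterHead: %d -> %d (SiLU) -> %d clusters (softmax)\n",
              x$p, x$hidden, x$K))
  invisible(x)
}

## forward with caches for backprop; inputs are standardized with the
## statistics frozen into the head at training time
headForward <- function(head, X) {
  X <- sweep(sweep(X, 2L, head$center), 2L, head$scale, "/")
  Z1 <- X %*% head$W1 + rep(head$b1, each = nrow(X))
  S <- 1 / (1 + exp(-Z1))
  A1 <- Z1 * S
  Z2 <- A1 %*% head$W2 + rep(head$b2, each = nrow(X))
  Z2 <- Z2 - apply(Z2, 1L, max)
  P <- exp(Z2)
  P <- P / rowSums(P)
  list(P = P, X = X, Z1 = Z1, S = S, A1 = A1)
}

## backprop dL/dZ2 (post-softmax logit gradient) to parameter gradients
headBackward <- function(head, fw, dZ2) {
  dA1 <- dZ2 %*% t(head$W2)
  dZ1 <- dA1 * (fw$S * (1 + fw$Z1 * (1 - fw$S)))
  list(W1 = crossprod(fw$X, dZ1), b1 = colSums(dZ1),
       W2 = crossprod(fw$A1, dZ2), b2 = colSums(dZ2))
}

#' Soft cluster assignment of feature rows
#'
#' @param head a [clusterHead()].
#' @param features n x p numeric matrix (rows are [latentFeatures()]).
#' @return n x K probability matrix.
#' @export
softAssign <- function(head, features) {
  headForward(head, as.matrix(features))$P
}

#' Train the clustering head by information maximization
#'
#' Full-batch gradient ascent (Adam) on
#' `mutualInfo - muSat * satLoss`. The SAT term uses positionally paired
#' augmented features (e.g. features of rotated/translated/rescaled tiles
#' re-encoded through the frozen autoencoder); when `augmented` is `NULL`
#' the consistency term is dropped.
#'
#' @param features n x p feature matrix.
#' @param K number of clusters (2 <= K <= n).
#' @param augmented optional n x p matrix of augmented-feature pairs.
#' @param muSat weight of the SAT consistency term.
#' @param iters gradient steps.
#' @param lr Adam learning rate.
#' @param hidden hidden width of the head.
#' @param seed RNG seed (initialization).
#' @param head optionally, an existing head to continue training.
#' @return a list with `head`, `probs` (final n x K assignment), `labels`
#'   (0-based hard labels) and `trace` (per-iteration objective
#'   `data.frame`: iter, h_marginal, h_conditional, mutual_info, sat_loss,
#'   total).
#' @export
trainClustering <- function(features, K, augmented = NULL, muSat = 1.0,
                            iters = 300L, lr = 5e-3, hidden = 64L,
                            seed = 1L, head = NULL) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (K < 2L || K > n)
    stop("invalid argument: need n >= K >= 2 (n = ", n, ", K = ", K, ")")
  if (!is.null(augmented)) {
    augmented <- as.matrix(augmented)
    if (!identical(dim(augmented), dim(X)))
      stop("invalid argument: augmented features must pair with features")
  }
  if (is.null(head)) {
    head <- clusterHead(ncol(X), K, hidden, seed)
    head$center <- colMeans(X)
    sds <- apply(X, 2L, stats::sd)
    head$scale <- ifelse(is.finite(sds) & sds > 1e-12, sds, 1)
  }
  state <- adamInit(head[c("W1", "b1", "W2", "b2")])
  rows <- vector("list", iters)
  for (it in seq_len(iters)) {
    fw <- headForward(head, X)
    P <- fw$P
    pbar <- colMeans(P)
    hMarg <- entropyNat(pbar)
    hCond <- mean(apply(P, 1L, entropyNat))
    mi <- hMarg - hCond
    ## dMI/dP = (log P - log pbar)/n; chain through softmax
    eps <- 1e-12
    dP <- (log(P + eps) - rep(log(pbar + eps), each = n)) / n
    dZ2 <- P * (dP - rowSums(dP * P))   # ascent direction on logits
    sat <- 0
    if (!is.null(augmented) && muSat > 0) {
      fwA <- headForward(head, augmented)
      sat <- satLoss(P, fwA$P)
      ## descent on KL(target || aug) w.r.t. augmented logits
      dZ2A <- -muSat * (fwA$P - P) / n
      gA <- headBackward(head, fwA, dZ2A)
    }
    g <- headBackward(head, fw, dZ2)
    if (!is.null(augmented) && muSat > 0)
      g <- mapTree2(g, gA, `+`)
    total <- mi - muSat * sat
    if (!is.finite(total))
      stop("non-finite clustering objective at iteration ", it)
    ## Adam maximizes by stepping along -(-g)
    upd <- adamStep(head[c("W1", "b1", "W2", "b2")],
                    mapTree(g, function(x) -x), state, lr = lr)
    head[c("W1", "b1", "W2", "b2")] <- upd$params
    state <- upd$state
    rows[[it]] <- data.frame(iter = it, h_marginal = hMarg,
                             h_conditional = hCond, mutual_info = mi,
                             sat_loss = sat, total = total)
  }
  P <- softAssign(head, X)
  list(head = head, probs = P, labels = hardLabels(P),
       trace = do.call(rbind, rows))
}

## ---- tile augmentations for SAT ----

#' Random tile augmentation (rotation, translation, scaling)
#'
#' Applies a 90-degree rotation multiple, an integer circular translation,
#' and a +/-10% rescale (nearest-neighbor, recropped/padded to the original
#' size) -- the transformation family under which cluster assignments are
#' asked to stay consistent.
#'
#' @param tile `H x W x 3` array.
#' @param seed RNG seed.
#' @return an augmented tile of the same shape.
#' @export
augmentTile <- function(tile, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    s <- dim(tile)[1]
    rot <- sample(0:3, 1L)
    out <- tile
    if (rot > 0) for (r in seq_len(rot))
      out <- aperm(out, c(2, 1, 3))[s:1, , , drop = FALSE]
    sh <- sample(seq.int(-(s %/% 8L), s %/% 8L), 2L, replace = TRUE)
    if (sh[1] != 0) out <- out[c((sh[1] %% s + 1L):s, seq_len(sh[1] %% s)), , ,
                               drop = FALSE]
    if (sh[2] != 0) out <- out[, c((sh[2] %% s + 1L):s, seq_len(sh[2] %% s)), ,
                               drop = FALSE]
    sc <- stats::runif(1, 0.9, 1.1)
    ns <- max(8L, round(s * sc))
    map <- pmin(pmax(round(seq(1, s, length.out = ns)), 1L), s)
    scaled <- out[map, map, , drop = FALSE]
    if (ns >= s) {
      off <- (ns - s) %/% 2L
      out <- scaled[off + seq_len(s), off + seq_len(s), , drop = FALSE]
    } else {
      padded <- array(0, dim(tile))
      off <- (s - ns) %/% 2L
      padded[off + seq_len(ns), off + seq_len(ns), ] <- scaled
      out <- padded
    }
    out
  })
}
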