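## Minimal convolutional-network core with explicit forward/backward passes.
##
## There is no automatic-differentiation framework in the package's
## dependency set, so the layers used by the autoencoder, discriminator,
## feature extractor and latent denoiser are implemented directly:
## convolution via im2col + BLAS matrix products, with hand-derived
## gradients. Tensors are column-major R arrays [H, W, C, N] (channel-third,
## batch-last); kernels are stored as [kh*kw*cin, cout] matrices.
##
## The layer vocabulary is deliberately small: conv, silu, tanh, nearest
## upsample, and a two-conv residual block. Gradient correctness is pinned
## by finite-difference tests.

.im2colCache <- new.env(parent = emptyenv())

## Index map from output-position rows to padded-input linear indices, for a
## single sample of shape [Hp, Wp, C]. Cached per configuration.
im2colIndex <- function(H, W, C, kh, kw, stride, pad) {
  key <- paste(H, W, C, kh, kw, stride, pad, sep = "_")
  if (!is.null(.im2colCache[[key]])) return(.im2colCache[[key]])
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  outH <- (Hp - kh) %/% stride + 1L
  outW <- (Wp - kw) %/% stride + 1L
  hh <- (rep(seq_len(outH), times = outW) - 1L) * stride
  ww <- (rep(seq_len(outW), each = outH) - 1L) * stride
  dh <- rep(seq_len(kh), times = kw * C)
  dw <- rep(rep(seq_len(kw), each = kh), times = C)
  cc <- rep(seq_len(C), each = kh * kw)
  rowPart <- hh + Hp * ww
  colPart <- dh + Hp * (dw - 1L) + Hp * Wp * (cc - 1L)
  idx <- outer(rowPart, colPart, "+")
  res <- list(idx = idx, outH = outH, outW = outW, Hp = Hp, Wp = Wp)
  assign(key, res, envir = .im2colCache)
  res
}

## He-scaled random conv layer; weights [kh*kw*cin, cout].
makeConv <- function(kh, cin, cout, stride = 1L, pad = (kh - 1L) %/% 2L,
                     scale = 1) {
  fanIn <- kh * kh * cin
  list(type = "conv",
       W = matrix(stats::rnorm(fanIn * cout, sd = scale * sqrt(2 / fanIn)),
                  fanIn, cout),
       b = numeric(cout),
       kh = kh, kw = kh, cin = cin, cout = cout,
       stride = as.integer(stride), pad = as.integer(pad))
}

padInput <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

convForward <- function(x, cv) {
  d <- dim(x)
  if (d[3] != cv$cin)
    stop("conv expects ", cv$cin, " input channels, got ", d[3])
  ii <- im2colIndex(d[1], d[2], d[3], cv$kh, cv$kw, cv$stride, cv$pad)
  xp <- padInput(x, cv$pad)
  N <- d[4]
  outP <- ii$outH * ii$outW
  kk <- ncol(ii$idx)
  P <- matrix(0, outP * N, kk)
  for (n in seq_len(N)) {
    xn <- xp[, , , n]
    P[(n - 1L) * outP + seq_len(outP), ] <- xn[ii$idx]
  }
  outM <- P %*% cv$W
  outM <- outM + rep(cv$b, each = nrow(outM))
  out <- array(0, c(ii$outH, ii$outW, cv$cout, N))
  for (n in seq_len(N))
    out[, , , n] <- outM[(n - 1L) * outP + seq_len(outP), ]
  list(out = out, cache = list(P = P, ii = ii, inDim = d))
}

convBackward <- function(dout, cv, cache) {
  ii <- cache$ii
  d <- cache$inDim
  N <- d[4]
  outP <- ii$outH * ii$outW
  doutM <- matrix(0, outP * N, cv$cout)
  for (n in seq_len(N))
    doutM[(n - 1L) * outP + seq_len(outP), ] <- dout[, , , n]
  dW <- crossprod(cache$P, doutM)
  db <- colSums(doutM)
  dP <- doutM %*% t(cv$W)
  dx <- array(0, d)
  grp <- as.vector(ii$idx)
  padLen <- ii$Hp * ii$Wp * d[3]
  for (n in seq_len(N)) {
    v <- as.vector(dP[(n - 1L) * outP + seq_len(outP), ])
    acc <- rowsum(v, grp)
    dxp <- numeric(padLen)
    dxp[as.integer(rownames(acc))] <- acc
    dim(dxp) <- c(ii$Hp, ii$Wp, d[3])
    dx[, , , n] <- dxp[cv$pad + seq_len(d[1]), cv$pad + seq_len(d[2]), ,
                       drop = FALSE]
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

siluForward <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(out = x * s, cache = list(x = x, s = s))
}

siluBackward <- function(dout, cache) {
  s <- cache$s
  dout * (s * (1 + cache$x * (1 - s)))
}

upsampleForward <- function(x) {
  d <- dim(x)
  ih <- rep(seq_len(d[1]), each = 2L)
  out <- x[ih, , , , drop = FALSE][, rep(seq_len(d[2]), each = 2L), , ,
                                   drop = FALSE]
  list(out = out, cache = list(inDim = d))
}

upsampleBackward <- function(dout, cache) {
  d <- cache$inDim
  dx <- array(0, d)
  for (a in 1:2) for (b in 1:2)
    dx <- dx + dout[seq(a, by = 2L, length.out = d[1]),
                    seq(b, by = 2L, length.out = d[2]), , , drop = FALSE]
  dx
}

## Residual block: out = x + conv2(silu(conv1(x))), channel-preserving.
makeResBlock <- function(channels, scale2 = 0.3) {
  list(type = "res",
       conv1 = makeConv(3L, channels, channels),
       conv2 = makeConv(3L, channels, channels, scale = scale2))
}

resForward <- function(x, blk) {
  f1 <- convForward(x, blk$conv1)
  a1 <- siluForward(f1$out)
  f2 <- convForward(a1$out, blk$conv2)
  list(out = x + f2$out, cache = list(c1 = f1$cache, a1 = a1$cache,
                                      c2 = f2$cache))
}

resBackward <- function(dout, blk, cache) {
  b2 <- convBackward(dout, blk$conv2, cache$c2)
  da1 <- siluBackward(b2$dx, cache$a1)
  b1 <- convBackward(da1, blk$conv1, cache$c1)
  list(dx = dout + b1$dx,
       grads = list(conv1 = b1$grads, conv2 = b2$grads))
}

## ---- sequential network executor ----

seqForward <- function(x, layers) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    r <- switch(ly$type,
                conv = convForward(x, ly),
                silu = siluForward(x),
                tanh = list(out = tanh(x), cache = list()),
                up = upsampleForward(x),
                res = resForward(x, ly),
                stop("unknown layer type: ", ly$type))
    if (ly$type == "tanh") r$cache <- list(out = r$out)
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(out = x, caches = caches)
}

seqBackward <- function(dout, layers, caches) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      r <- convBackward(dout, ly, caches[[i]])
      grads[[i]] <- r$grads
      dout <- r$dx
    } else if (ly$type == "silu") {
      dout <- siluBackward(dout, caches[[i]])
    } else if (ly$type == "tanh") {
      dout <- dout * (1 - caches[[i]]$out^2)
    } else if (ly$type == "up") {
      dout <- upsampleBackward(dout, caches[[i]])
    } else if (ly$type == "res") {
      r <- resBackward(dout, ly, caches[[i]])
      grads[[i]] <- r$grads
      dout <- r$dx
    }
  }
  list(dx = dout, grads = grads)
}

## ---- nested-parameter optimizers ----
##
## Parameters and gradients are parallel nested lists whose numeric leaves
## are updated in place-by-copy. States mirror the structure.

mapTree <- function(tree, fn) {
  if (is.numeric(tree)) return(fn(tree))
  if (is.list(tree)) return(lapply(tree, mapTree, fn = fn))
  tree
}

## Walks params/grads/two state trees in parallel, applying `leafFn` at
## numeric leaves; returns list(params, s1, s2). Subtrees are matched by
## name when both trees are named (layer lists carry non-parameter fields
## like kernel geometry that must not be touched), positionally otherwise;
## leaves without a matching gradient are left unchanged.
walkUpdate <- function(params, grads, s1, s2, leafFn) {
  if (is.numeric(params)) {
    if (is.null(grads)) return(list(p = params, s1 = s1, s2 = s2))
    return(leafFn(params, grads, s1, s2))
  }
  if (!is.list(params) || is.null(grads))
    return(list(p = params, s1 = s1, s2 = s2))
  byName <- !is.null(names(params)) && !is.null(names(grads))
  outP <- params; outS1 <- s1; outS2 <- s2
  for (i in seq_along(params)) {
    key <- if (byName) names(params)[i] else i
    g <- if (byName) {
      if (key %in% names(grads)) grads[[key]] else NULL
    } else if (is.list(grads) && length(grads) >= i) grads[[i]] else NULL
    if (is.null(g)) next
    r <- walkUpdate(params[[i]], g,
                    if (is.list(s1)) s1[[i]] else NULL,
                    if (is.list(s2)) s2[[i]] else NULL, leafFn)
    outP[[i]] <- r$p
    outS1[[i]] <- r$s1
    outS2[[i]] <- r$s2
  }
  list(p = outP, s1 = outS1, s2 = outS2)
}

#' @noRd
adamInit <- function(params) {
  list(m = mapTree(params, function(x) x * 0),
       v = mapTree(params, function(x) x * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  r <- walkUpdate(params, grads, state$m, state$v,
                  function(p, g, m, v) {
                    if (is.null(m)) { m <- p * 0; v <- p * 0 }
                    m <- beta1 * m + (1 - beta1) * g
                    v <- beta2 * v + (1 - beta2) * g^2
                    list(p = p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                         s1 = m, s2 = v)
                  })
  list(params = r$p, state = list(m = r$s1, v = r$s2, t = state$t))
}

adadeltaInit <- function(params) {
  list(eg = mapTree(params, function(x) x * 0),
       ed = mapTree(params, function(x) x * 0))
}

adadeltaStep <- function(params, grads, state, lr = 1, rho = 0.95,
                         eps = 1e-6) {
  r <- walkUpdate(params, grads, state$eg, state$ed,
                  function(p, g, eg, ed) {
                    if (is.null(eg)) { eg <- p * 0; ed <- p * 0 }
                    eg <- rho * eg + (1 - rho) * g^2
                    upd <- sqrt(ed + eps) / sqrt(eg + eps) * g
                    ed <- rho * ed + (1 - rho) * upd^2
                    list(p = p - lr * upd, s1 = eg, s2 = ed)
                  })
  list(params = r$p, state = list(eg = r$s1, ed = r$s2))
}

## Build an optimizer closure by name ("adam" or "adadelta").
makeOptimizer <- function(name, params, lr) {
  name <- match.arg(name, c("adam", "adadelta"))
  if (name == "adam") {
    state <- adamInit(params)
    function(params, grads) {
      r <- adamStep(params, grads, state, lr = lr)
      state <<- r$state
      r$params
    }
  } else {
    state <- adadeltaInit(params)
    function(params, grads) {
      r <- adadeltaStep(params, grads, state, lr = lr)
      state <<- r$state
      r$params
    }
  }
}

## Batch helpers: stack a list of [H,W,C] arrays into [H,W,C,N] and back.
stackTiles <- function(tileList) {
  d <- dim(tileList[[1]])
  out <- array(0, c(d, length(tileList)))
  for (n in seq_along(tileList)) out[, , , n] <- tileList[[n]]
  out
}

unstackTiles <- function(x) {
  N <- dim(x)[4]
  lapply(seq_len(N), function(n) x[, , , n])
}
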