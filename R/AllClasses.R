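#' @import methods
NULL

#' TileSet: an ordered collection of square RGB image tiles
#'
#' Tiles are stored as `H x W x 3` numeric arrays with values in [0, 1]
#' (channel-last, the package-wide pixel convention; models rescale to
#' [-1, 1] internally at their own boundary). Labels, when present, are
#' 0-based integer phenotype/cluster IDs and carry fixture ground truth;
#' their absence is the normal unlabeled regime.
#'
#' @slot tiles list of `H x W x 3` numeric arrays in [0, 1], all the same size.
#' @slot ids character vector of stable per-tile identifiers.
#' @slot labels integer vector of 0-based class labels (length 0 if unlabeled).
#' @slot split character scalar, `"train"` or `"test"`.
#' @seealso [generateTileSet()], [readTiles()], [writeTiles()]
#' @export
setClass("TileSet", representation(
  tiles = "list",
  ids = "character",
  labels = "integer",
  split = "character"
))

setValidity("TileSet", function(object) {
  n <- length(object@tiles)
  if (length(object@ids) != n)
    return("ids must have one entry per tile")
  if (anyDuplicated(object@ids))
    return("ids must be unique")
  if (length(object@labels) && length(object@labels) != n)
    return("labels, when present, must have one entry per tile")
  if (length(object@labels) && any(object@labels < 0L))
    return("labels must be non-negative (0-based class IDs)")
  if (!object@split %in% c("train", "test"))
    return("split must be 'train' or 'test'")
  for (i in seq_len(n)) {
    tl <- object@tiles[[i]]
    d <- dim(tl)
    if (!is.numeric(tl) || length(d) != 3L || d[3] != 3L)
      return(sprintf("tile %d is not an H x W x 3 numeric array", i))
    if (d[1] != d[2])
      return(sprintf("tile %d is not square (%d x %d)", i, d[1], d[2]))
    if (anyNA(tl) || min(tl) < 0 || max(tl) > 1)
      return(sprintf("tile %d has pixel values outside [0, 1]", i))
  }
  if (n > 1L) {
    sizes <- vapply(object@tiles, function(t) dim(t)[1], numeric(1))
    if (length(unique(sizes)) != 1L)
      return("all tiles must have the same size")
  }
  TRUE
})

#' Codebook: the discrete latent embedding table of the VQ autoencoder
#'
#' @slot vectors numeric matrix, one codebook vector per row
#'   (`K_cb` rows of dimension `d`; defaults follow the study scale,
#'   128 vectors of dimension 16).
#' @export
setClass("Codebook", representation(vectors = "matrix"))

setValidity("Codebook", function(object) {
  v <- object@vectors
  if (!is.numeric(v) || nrow(v) < 2L)
    return("codebook needs a numeric matrix with at least 2 rows")
  if (anyNA(v) || any(!is.finite(v)))
    return("codebook vectors must be finite")
  TRUE
})

#' QuantizedLatent: a latent grid snapped to its nearest codebook vectors
#'
#' @slot indices integer matrix (`h x w`) of 0-based codebook row indices.
#' @slot embedded numeric array (`h x w x d`); `embedded[i, j, ]` is exactly
#'   the codebook row selected by `indices[i, j]`.
#' @export
setClass("QuantizedLatent", representation(
  indices = "matrix",
  embedded = "array"
))

setValidity("QuantizedLatent", function(object) {
  d <- dim(object@embedded)
  if (length(d) != 3L)
    return("embedded must be an h x w x d array")
  if (!identical(dim(object@indices), d[1:2]))
    return("indices must be an h x w matrix matching embedded")
  if (any(object@indices < 0L))
    return("indices must be non-negative (0-based)")
  TRUE
})

#' NoiseSchedule: the forward-diffusion variance schedule
#'
#' Holds \eqn{\beta_t}, \eqn{\alpha_t = 1 - \beta_t} and the cumulative
#' products \eqn{\bar\alpha_t = \prod_{s \le t} \alpha_s} for `nSteps`
#' timesteps. For the linear schedule the betas increase strictly and the
#' alpha-bars decrease strictly, all within (0, 1).
#'
#' @slot nSteps integer, number of diffusion timesteps T.
#' @slot betas numeric vector of length T in (0, 1).
#' @slot alphas numeric vector, `1 - betas`.
#' @slot alphaBars numeric vector, `cumprod(alphas)`.
#' @seealso [linearSchedule()]
#' @export
setClass("NoiseSchedule", representation(
  nSteps = "integer",
  betas = "numeric",
  alphas = "numeric",
  alphaBars = "numeric"
))

setValidity("NoiseSchedule", function(object) {
  T <- object@nSteps
  if (T < 1L) return("nSteps must be >= 1")
  if (length(object@betas) != T || length(object@alphas) != T ||
      length(object@alphaBars) != T)
    return("betas, alphas and alphaBars must all have length nSteps")
  if (any(object@betas <= 0) || any(object@betas >= 1))
    return("betas must lie in (0, 1)")
  if (max(abs(object@alphas - (1 - object@betas))) > 1e-12)
    return("alphas must equal 1 - betas")
  if (max(abs(object@alphaBars - cumprod(object@alphas))) > 1e-12)
    return("alphaBars must equal cumprod(alphas)")
  TRUE
})
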