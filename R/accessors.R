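#' @include AllClasses.R
NULL

#' Construct a TileSet
#'
#' @param tiles list of `H x W x 3` numeric arrays in [0, 1].
#' @param ids character identifiers (defaults to zero-padded `tile_<i>`).
#' @param labels optional integer 0-based class labels.
#' @param split `"train"` or `"test"`.
#' @return a [TileSet-class] object.
#' @export
TileSet <- function(tiles, ids = NULL, labels = NULL, split = "train") {
  if (is.null(ids))
    ids <- sprintf("tile_%04d", seq_along(tiles) - 1L)
  new("TileSet", tiles = tiles, ids = as.character(ids),
      labels = if (is.null(labels)) integer(0) else as.integer(labels),
      split = split)
}

#' @describeIn TileSet number of tiles
#' @param x a `TileSet`.
#' @export
setMethod("length", "TileSet", function(x) length(x@tiles))

#' Accessors for TileSet
#'
#' @param x a [TileSet-class].
#' @return `tiles()` the list of pixel arrays; `tileIds()` the identifiers;
#'   `tileLabels()` the 0-based labels (`NULL` if unlabeled); `tileSize()` the
#'   common tile side length.
#' @name tileset-accessors
NULL

#' @rdname tileset-accessors
#' @export
tiles <- function(x) x@tiles

#' @rdname tileset-accessors
#' @export
tileIds <- function(x) x@ids

#' @rdname tileset-accessors
#' @export
tileLabels <- function(x) if (length(x@labels)) x@labels else NULL

#' @rdname tileset-accessors
#' @export
tileSize <- function(x) {
  if (!length(x@tiles)) return(NA_integer_)
  dim(x@tiles[[1]])[1]
}

#' Subset a TileSet
#' @param x a `TileSet`; @param i indices; @param j,...,drop ignored.
#' @export
setMethod("[", "TileSet", function(x, i, j, ..., drop = TRUE) {
  new("TileSet", tiles = x@tiles[i], ids = x@ids[i],
      labels = if (length(x@labels)) x@labels[i] else integer(0),
      split = x@split)
})

setMethod("show", "TileSet", function(object) {
  cat(sprintf("TileSet of %d tile(s), %dx%d px, split '%s'%s\n",
              length(object@tiles), tileSize(object), tileSize(object),
              object@split,
              if (length(object@labels))
                sprintf(", %d classes", length(unique(object@labels)))
              else ", unlabeled"))
})

#' Construct a Codebook
#'
#' @param vectors numeric matrix (rows are codebook vectors), or omit to draw
#'   a fresh random codebook.
#' @param nVectors,dim size of the random codebook when `vectors` is missing.
#' @param seed RNG seed for the random initialization.
#' @return a [Codebook-class].
#' @export
Codebook <- function(vectors = NULL, nVectors = 128L, dim = 16L, seed = 1L) {
  if (is.null(vectors)) {
    vectors <- withr::with_seed(seed,
      matrix(stats::runif(nVectors * dim, -1, 1) / dim, nrow = nVectors))
  }
  new("Codebook", vectors = as.matrix(vectors))
}

#' @rdname Codebook
#' @param x a `Codebook`.
#' @export
codebookVectors <- function(x) x@vectors

setMethod("show", "Codebook", function(object) {
  cat(sprintf("Codebook: %d vectors of dimension %d\n",
              nrow(object@vectors), ncol(object@vectors)))
})

#' Accessors for QuantizedLatent
#' @param x a [QuantizedLatent-class].
#' @name quantized-accessors
NULL

#' @rdname quantized-accessors
#' @export
latentIndices <- function(x) x@indices

#' @rdname quantized-accessors
#' @export
latentEmbedded <- function(x) x@embedded

setMethod("show", "QuantizedLatent", function(object) {
  d <- dim(object@embedded)
  cat(sprintf("QuantizedLatent: %dx%d grid, embedding dim %d, %d distinct code(s)\n",
              d[1], d[2], d[3], length(unique(as.vector(object@indices)))))
})

setMethod("show", "NoiseSchedule", function(object) {
  cat(sprintf("NoiseSchedule: T = %d, beta in [%g, %g], alpha_bar_T = %.4g\n",
              object@nSteps, object@betas[1], object@betas[object@nSteps],
              object@alphaBars[object@nSteps]))
})
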