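## Tile dataset I/O: 8-bit RGB PNG per tile, CSV label sidecar
## ("id,label"; absent when the data are unlabeled), JSON manifest.

#' Write a TileSet to a directory
#'
#' One 8-bit RGB PNG per tile, named `<id>.png`; labels (if present) go to a
#' `labels.csv` sidecar with header `id,label`; a `manifest.json` records ids,
#' split and tile size.
#'
#' @param dataset a [TileSet-class].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
writeTiles <- function(dataset, path) {
  stopifnot(is(dataset, "TileSet"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset@tiles)) {
    png::writePNG(dataset@tiles[[i]],
                  file.path(path, paste0(dataset@ids[i], ".png")))
  }
  if (length(dataset@labels)) {
    utils::write.csv(data.frame(id = dataset@ids, label = dataset@labels),
                     file.path(path, "labels.csv"), row.names = FALSE)
  }
  manifest <- list(ids = dataset@ids, split = dataset@split,
                   size = tileSize(dataset), n = length(dataset@tiles))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a TileSet from a directory
#'
#' Reads every `*.png` in `path` in lexicographic id order; a `labels.csv`
#' sidecar (header `id,label`), when present, supplies the labels. Pixel
#' values round-trip through [writeTiles()] up to 8-bit quantization
#' (max abs error <= 1/255).
#'
#' @param path directory containing PNG tiles.
#' @param split split tag for the resulting dataset (taken from
#'   `manifest.json` when available).
#' @return a [TileSet-class].
#' @export
readTiles <- function(path, split = NULL) {
  if (!dir.exists(path)) stop("not a directory: ", path)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG tiles found in ", path)
  ids <- sub("\\.png$", "", basename(files))
  tilesList <- lapply(files, function(f) {
    px <- tryCatch(png::readPNG(f), error = function(e)
      stop("I/O error reading '", f, "': ", conditionMessage(e), call. = FALSE))
    if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
    if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
    if (dim(px)[1] != dim(px)[2])
      stop("invalid format: non-square image '", f, "' (",
           dim(px)[1], "x", dim(px)[2], ")", call. = FALSE)
    px
  })
  labels <- NULL
  labFile <- file.path(path, "labels.csv")
  if (file.exists(labFile)) {
    lab <- utils::read.csv(labFile, stringsAsFactors = FALSE)
    labels <- lab$label[match(ids, lab$id)]
    if (anyNA(labels))
      stop("labels.csv does not cover all tile ids in ", path)
  }
  if (is.null(split)) {
    manFile <- file.path(path, "manifest.json")
    split <- if (file.exists(manFile))
      jsonlite::read_json(manFile)$split else "train"
  }
  TileSet(tilesList, ids = ids, labels = labels, split = split)
}
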