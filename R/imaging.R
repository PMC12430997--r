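#' Read an RGB field image
#'
#' Reads a 3-channel PNG, JPEG or TIFF. 8-bit sources keep `uint8`
#' semantics (integer-valued pixels in `[0, 255]`); 16-bit sources are
#' rescaled to the `unit` scale by division by 65535. A fourth (alpha)
#' channel is dropped; grayscale input is rejected. The original bit depth
#' is recorded in the image metadata.
#'
#' @param path file path; format is inferred from the extension.
#' @param id image identifier; defaults to the file name sans extension.
#' @return An [RGBImage-class].
#' @export
readRGBImage <- function(path, id = NULL) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  if (is.null(id)) id <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    bits <- attr(arr, "info")$bit.depth
    if (is.null(bits)) bits <- 8L
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)  # values normalized to [0,1]
    bits <- attr(arr, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else if (ext %in% c("jpg", "jpeg")) {
    ebi <- EBImage::readImage(path)
    arr <- aperm(EBImage::imageData(ebi), c(2, 1, 3))
    bits <- 8L
  } else {
    stop("unsupported image format: .", ext, " (use PNG, JPEG or TIFF)")
  }
  if (length(dim(arr)) == 2L)
    stop("invalid input: expected 3 channels, got 1 (grayscale image)")
  nc <- dim(arr)[3]
  if (nc == 4L) arr <- arr[, , 1:3, drop = FALSE]
  else if (nc != 3L)
    stop("invalid input: expected 3 channels, got ", nc)
  if (bits <= 8L) {
    RGBImage(round(arr * 255), scale = "uint8", id = id,
             meta = list(bit_depth = as.integer(bits), path = path))
  } else {
    RGBImage(arr, scale = "unit", id = id,
             meta = list(bit_depth = as.integer(bits), path = path))
  }
}

#' Normalize image channels
#'
#' `unit` divides by the scale maximum (255 for `uint8`, identity for
#' already-unit images); `chromatic` maps each pixel to its chromatic
#' coordinates `(R, G, B) / (R + G + B)` with the all-zero pixel mapped to
#' `(0, 0, 0)`; `none` is the identity. Vegetation indices are computed on
#' unit-scaled channels by default because downstream thresholding is
#' data-driven (multi-Otsu) and hence scale-robust.
#'
#' @param img an [RGBImage-class].
#' @param mode one of `"unit"`, `"chromatic"`, `"none"`.
#' @return An [RGBImage-class] on the `unit` scale (or unchanged for
#'   `"none"`).
#' @export
normalizeImage <- function(img, mode = c("unit", "chromatic", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(img)
  px <- img@pixels
  if (mode == "unit") {
    if (img@scale == "uint8") px <- px / 255
    return(RGBImage(px, scale = "unit", id = img@id, meta = img@meta))
  }
  tot <- px[, , 1] + px[, , 2] + px[, , 3]
  safe <- ifelse(tot == 0, 1, tot)
  for (k in 1:3) px[, , k] <- px[, , k] / safe
  RGBImage(px, scale = "unit", id = img@id, meta = img@meta)
}

indexFrom <- function(img, fun, name) {
  px <- img@pixels
  d <- dim(px)
  v <- matrix(fun(px[, , 1], px[, , 2], px[, , 3]), d[1], d[2])
  new("IndexMap", values = v, indexName = name, sourceId = img@id)
}

#' Excess-green-minus-excess-red vegetation index
#'
#' Per-pixel `ExGR = 3 G - 2.4 R - B`, the index driving stage-one prompt
#' generation: it is strongly positive over green canopy and negative over
#' soil and water.
#'
#' @param img an [RGBImage-class], already normalized as configured.
#' @return An [IndexMap-class] named `"ExGR"`.
#' @export
exgr <- function(img) indexFrom(img, function(r, g, b) 3 * g - 2.4 * r - b,
                                "ExGR")

#' Excess-green vegetation index
#'
#' Per-pixel `ExG = 2 G - R - B`; used as a spectral feature of each
#' segmented seedling (low values suggest stress or chlorosis).
#'
#' @inheritParams exgr
#' @return An [IndexMap-class] named `"ExG"`.
#' @export
exg <- function(img) indexFrom(img, function(r, g, b) 2 * g - r - b, "ExG")

#' Luminance (grayscale) map
#'
#' ITU-R BT.601 luminance `0.299 R + 0.587 G + 0.114 B`, on the same scale
#' as the input; the grayscale base of the co-occurrence texture features.
#'
#' @inheritParams exgr
#' @return An [IndexMap-class] named `"gray"`.
#' @export
toGray <- function(img)
  indexFrom(img, function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b, "gray")

#' Write an index map to disk
#'
#' With a `.tif`/`.tiff` extension, writes a single-channel 32-bit TIFF
#' holding the values affinely rescaled to `[0, 1]`, plus a `<path>.json`
#' sidecar recording the original `(min, max)` so the map is exactly
#' recoverable; with `.csv`, writes the raw values as a plain-text matrix.
#'
#' @param map an [IndexMap-class].
#' @param path output path ending in `.tif`/`.tiff` or `.csv`.
#' @return `path`, invisibly.
#' @export
writeIndexMap <- function(map, path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("tif", "tiff")) {
    lo <- min(map@values); hi <- max(map@values)
    span <- if (hi > lo) hi - lo else 1
    tiff::writeTIFF((map@values - lo) / span, path, bits.per.sample = 32L)
    jsonlite::write_json(list(index_name = map@indexName, min = lo,
                              max = hi, source_id = map@sourceId),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else if (ext == "csv") {
    utils::write.table(map@values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else stop("unsupported output format: .", ext)
  invisible(path)
}
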