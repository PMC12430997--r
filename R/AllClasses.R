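#' @import methods
#' @importFrom stats var sd dist lm coef predict rnorm runif setNames
#' @importFrom utils head write.csv read.csv
NULL

#' RGBImage: a three-channel field image
#'
#' The raw input of the pipeline: an `H x W x 3` numeric array in fixed
#' (Red, Green, Blue) channel order, together with the declared value scale.
#' 8-bit sources keep `uint8` semantics (values in `[0, 255]`); 16-bit and
#' normalized sources use the `unit` scale (`[0, 1]`).
#'
#' @slot pixels numeric array, `H x W x 3`, channel order (R, G, B).
#' @slot scale character, `"uint8"` or `"unit"`.
#' @slot id character identifier (propagated into downstream artifacts).
#' @slot meta list of source metadata (e.g. original bit depth).
#' @exportClass RGBImage
setClass("RGBImage",
  representation(pixels = "array", scale = "character", id = "character",
                 meta = "list"),
  prototype(scale = "unit", id = "", meta = list()))

setValidity("RGBImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L)
    return("image must have H >= 1 and W >= 1")
  if (!all(is.finite(object@pixels)))
    return("pixel values must all be finite")
  if (!object@scale %in% c("uint8", "unit"))
    return("scale must be 'uint8' or 'unit'")
  hi <- if (object@scale == "uint8") 255 else 1
  rng <- range(object@pixels)
  if (rng[1] < 0 || rng[2] > hi)
    return(sprintf("pixel values [%g, %g] outside declared %s range [0, %g]",
                   rng[1], rng[2], object@scale, hi))
  TRUE
})

#' Construct an RGBImage
#'
#' @param pixels `H x W x 3` numeric array (R, G, B).
#' @param scale `"uint8"` or `"unit"`.
#' @param id identifier string.
#' @param meta optional metadata list.
#' @return An [RGBImage-class] object.
#' @export
RGBImage <- function(pixels, scale = c("unit", "uint8"), id = "image",
                     meta = list()) {
  scale <- match.arg(scale)
  new("RGBImage", pixels = pixels, scale = scale, id = id, meta = meta)
}

#' IndexMap: a per-pixel scalar index
#'
#' Holds a vegetation index (ExGR, ExG) or a luminance map derived from an
#' [RGBImage-class]; same height and width as its source.
#'
#' @slot values numeric `H x W` matrix.
#' @slot indexName character, e.g. `"ExGR"`, `"ExG"`, `"gray"`.
#' @slot sourceId id of the source image.
#' @exportClass IndexMap
setClass("IndexMap",
  representation(values = "matrix", indexName = "character",
                 sourceId = "character"))

setValidity("IndexMap", function(object) {
  if (!is.numeric(object@values)) return("values must be numeric")
  if (!all(is.finite(object@values))) return("index values must be finite")
  TRUE
})

#' BinaryMap: thresholded vegetation candidates
#'
#' @slot mask logical `H x W` matrix; `TRUE` marks candidate vegetation
#'   (the most-vegetated multi-Otsu class).
#' @slot thresholds numeric vector of the thresholds used (index units).
#' @slot nClasses integer number of Otsu classes.
#' @exportClass BinaryMap
setClass("BinaryMap",
  representation(mask = "matrix", thresholds = "numeric",
                 nClasses = "integer"))

setValidity("BinaryMap", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  TRUE
})

#' PromptSet: per-seedling boxes and point prompts
#'
#' One row per retained connected component: the tight bounding box
#' (half-open on the max edges, 0-based `(row, col)` coordinates) and its
#' geometric center, the point handed to the segmenter.
#'
#' @slot boxes numeric `n x 4` matrix, columns `row_min, col_min, row_max,
#'   col_max`.
#' @slot points numeric `n x 2` matrix of `(row, col)` centers.
#' @slot componentIds integer component labels.
#' @slot sourceId id of the source image.
#' @exportClass PromptSet
setClass("PromptSet",
  representation(boxes = "matrix", points = "matrix",
                 componentIds = "integer", sourceId = "character"))

setValidity("PromptSet", function(object) {
  n <- nrow(object@boxes)
  if (nrow(object@points) != n || length(object@componentIds) != n)
    return("boxes, points and componentIds must agree in length")
  if (n > 0) {
    b <- object@boxes; p <- object@points
    if (any(p[, 1] < b[, 1] | p[, 1] >= b[, 3] |
            p[, 2] < b[, 2] | p[, 2] >= b[, 4]))
      return("every point must lie inside its box")
  }
  TRUE
})

#' InstanceSegmentation: per-seedling instance masks
#'
#' `labelMap` is the single source of truth after overlap resolution:
#' value `k > 0` marks instance `k`, `0` background. Per-instance metadata
#' (prompt point, backend score) lives in `instanceInfo`.
#'
#' @slot labelMap integer `H x W` matrix, values `0..K`.
#' @slot instanceInfo data.frame with columns `instance_id`, `prompt_row`,
#'   `prompt_col`, `score`, `area_px`.
#' @slot sourceId id of the segmented image.
#' @exportClass InstanceSegmentation
setClass("InstanceSegmentation",
  representation(labelMap = "matrix", instanceInfo = "data.frame",
                 sourceId = "character"))

setValidity("InstanceSegmentation", function(object) {
  k <- nrow(object@instanceInfo)
  labs <- sort(unique(as.vector(object@labelMap)))
  labs <- labs[labs > 0]
  if (k > 0 && !identical(as.integer(labs), seq_len(k)))
    return("labelMap instance ids must be consecutive 1..K")
  if (k == 0 && length(labs) > 0)
    return("labelMap has labels but instanceInfo is empty")
  TRUE
})

#' FeatureTable: one 15-feature row per seedling
#'
#' Five morphological (area, perimeter, solidity, eccentricity,
#' circularity), four spectral (mean R, G, B, mean ExG) and six textural
#' (GLCM contrast, dissimilarity, homogeneity, energy, correlation, second
#' moment) descriptors per segmented seedling, in a fixed column order.
#'
#' @slot table data.frame: `instance_id`, the 15 feature columns, and
#'   logical degeneracy flags (`flag_circularity`, `flag_correlation`,
#'   `flag_constant`).
#' @slot scalingState `"raw"` or `"standardized"`.
#' @slot center,scale numeric vectors of per-feature mean and (population)
#'   sd recorded when standardized; empty otherwise.
#' @slot glcmConfig list echoing the GLCM settings used.
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(table = "data.frame", scalingState = "character",
                 center = "numeric", scale = "numeric", glcmConfig = "list"),
  prototype(scalingState = "raw", center = numeric(0), scale = numeric(0),
            glcmConfig = list()))

#' Names and order of the 15 seedling features
#' @return character vector of length 15.
#' @export
featureNames <- function() {
  c("area", "perimeter", "solidity", "eccentricity", "circularity",
    "mean_red", "mean_green", "mean_blue", "mean_exg",
    "glcm_contrast", "glcm_dissimilarity", "glcm_homogeneity",
    "glcm_energy", "glcm_correlation", "glcm_second_moment")
}

setValidity("FeatureTable", function(object) {
  if (!object@scalingState %in% c("raw", "standardized"))
    return("scalingState must be 'raw' or 'standardized'")
  missing <- setdiff(c("instance_id", featureNames()), names(object@table))
  if (length(missing))
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  if (anyNA(object@table[featureNames()]))
    return("feature columns must not contain missing values")
  TRUE
})

#' AnomalyResult: one-class SVM labels and model-selection log
#'
#' @slot instanceIds integer ids matching the feature table rows.
#' @slot labels integer vector, `+1` inlier / `-1` outlier.
#' @slot decisionValues numeric signed distances to the boundary; the sign
#'   always agrees with the label.
#' @slot bestParams list `(kernel, nu, gamma, degree)` selected by the
#'   silhouette grid search.
#' @slot silhouette numeric silhouette score of the selected partition.
#' @slot gridLog data.frame with one row per evaluated combination.
#' @slot seed integer seed recorded for reproducibility.
#' @exportClass AnomalyResult
setClass("AnomalyResult",
  representation(instanceIds = "integer", labels = "integer",
                 decisionValues = "numeric", bestParams = "list",
                 silhouette = "numeric", gridLog = "data.frame",
                 seed = "integer"))

setValidity("AnomalyResult", function(object) {
  if (!all(object@labels %in% c(-1L, 1L)))
    return("labels must be +1 or -1")
  if (length(object@labels) != length(object@decisionValues))
    return("labels and decisionValues lengths differ")
  ok <- ifelse(object@decisionValues >= 0, 1L, -1L) == object@labels
  if (!all(ok))
    return("sign(decisionValue) must agree with label")
  TRUE
})

#' SceneTruth: a synthetic paddy scene with ground truth
#'
#' @slot image the rendered [RGBImage-class].
#' @slot labelMap integer ground-truth instance map (pre-noise occupancy;
#'   draw order resolves overlaps).
#' @slot counts integer number of plants.
#' @slot anomalyIds integer ids of planted anomalous seedlings.
#' @slot params list: config echo and per-instance generative parameters.
#' @exportClass SceneTruth
setClass("SceneTruth",
  representation(image = "RGBImage", labelMap = "matrix",
                 counts = "integer", anomalyIds = "integer",
                 params = "list"))

setValidity("SceneTruth", function(object) {
  labs <- sort(unique(as.vector(object@labelMap)))
  labs <- labs[labs > 0]
  if (length(labs) != object@counts)
    return("counts must equal the number of distinct nonzero labels")
  if (!all(object@anomalyIds %in% labs))
    return("anomalyIds must be a subset of instance ids")
  TRUE
})

#' SegmenterBackend: the point-promptable segmenter contract
#'
#' A backend receives an [RGBImage-class] and a single `(row, col)` point
#' prompt and returns one or more candidate binary masks, each with a
#' confidence score in `[0, 1]`. Implementations: [fallbackBackend()]
#' (classical region growing on the ExGR map), [oracleBackend()]
#' (ground-truth lookup for synthetic scenes) and [foundationAdapter()]
#' (wrapper for an external promptable foundation model).
#'
#' @slot name backend name.
#' @exportClass SegmenterBackend
setClass("SegmenterBackend", representation("VIRTUAL", name = "character"))

#' @rdname SegmenterBackend-class
#' @exportClass FallbackBackend
setClass("FallbackBackend", contains = "SegmenterBackend",
  representation(config = "list", cache = "environment"))

#' @rdname SegmenterBackend-class
#' @exportClass OracleBackend
setClass("OracleBackend", contains = "SegmenterBackend",
  representation(truth = "SceneTruth"))

#' @rdname SegmenterBackend-class
#' @exportClass FoundationBackend
setClass("FoundationBackend", contains = "SegmenterBackend",
  representation(checkpoint = "character", modelType = "character",
                 predictor = "ANY"))
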