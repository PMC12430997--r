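#' Accessors for pipeline objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("imageScale", function(x) standardGeneric("imageScale"))
#' @rdname accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @rdname accessors
#' @export
setGeneric("indexValues", function(x) standardGeneric("indexValues"))
#' @rdname accessors
#' @export
setGeneric("vegetationMask", function(x) standardGeneric("vegetationMask"))
#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
#' @rdname accessors
#' @export
setGeneric("promptBoxes", function(x) standardGeneric("promptBoxes"))
#' @rdname accessors
#' @export
setGeneric("promptPoints", function(x) standardGeneric("promptPoints"))
#' @rdname accessors
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setGeneric("nInstances", function(x) standardGeneric("nInstances"))
#' @rdname accessors
#' @export
setGeneric("instanceInfo", function(x) standardGeneric("instanceInfo"))
#' @rdname accessors
#' @export
setGeneric("instanceMask", function(x, id) standardGeneric("instanceMask"))
#' @rdname accessors
#' @export
setGeneric("unionMask", function(x) standardGeneric("unionMask"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))
#' @rdname accessors
#' @export
setGeneric("scalingState", function(x) standardGeneric("scalingState"))
#' @rdname accessors
#' @export
setGeneric("anomalyLabels", function(x) standardGeneric("anomalyLabels"))
#' @rdname accessors
#' @export
setGeneric("decisionValues", function(x) standardGeneric("decisionValues"))
#' @rdname accessors
#' @export
setGeneric("bestParams", function(x) standardGeneric("bestParams"))
#' @rdname accessors
#' @export
setGeneric("gridLog", function(x) standardGeneric("gridLog"))
#' @rdname accessors
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))
#' @rdname accessors
#' @export
setGeneric("sceneCounts", function(x) standardGeneric("sceneCounts"))
#' @rdname accessors
#' @export
setGeneric("anomalyIds", function(x) standardGeneric("anomalyIds"))

#' Query a segmenter backend with one point prompt
#'
#' @param backend a [SegmenterBackend-class].
#' @param img the [RGBImage-class] being segmented.
#' @param point numeric `(row, col)` prompt, 0-based.
#' @return list with elements `masks` (list of logical `H x W` matrices)
#'   and `scores` (numeric in `[0, 1]`, same length).
#' @export
setGeneric("proposeMasks",
           function(backend, img, point) standardGeneric("proposeMasks"))

pixdim <- function(img) dim(img@pixels)[1:2]

#' @rdname accessors
setMethod("pixels", "RGBImage", function(x) x@pixels)
#' @rdname accessors
setMethod("imageScale", "RGBImage", function(x) x@scale)
#' @rdname accessors
setMethod("imageId", "RGBImage", function(x) x@id)
#' @rdname accessors
setMethod("indexValues", "IndexMap", function(x) x@values)
#' @rdname accessors
setMethod("vegetationMask", "BinaryMap", function(x) x@mask)
#' @rdname accessors
setMethod("thresholds", "BinaryMap", function(x) x@thresholds)
#' @rdname accessors
setMethod("promptBoxes", "PromptSet", function(x) x@boxes)
#' @rdname accessors
setMethod("promptPoints", "PromptSet", function(x) x@points)
#' @rdname accessors
setMethod("labelMap", "InstanceSegmentation", function(x) x@labelMap)
#' @rdname accessors
setMethod("labelMap", "SceneTruth", function(x) x@labelMap)
#' @rdname accessors
setMethod("nInstances", "InstanceSegmentation",
          function(x) nrow(x@instanceInfo))
#' @rdname accessors
setMethod("nInstances", "PromptSet", function(x) nrow(x@boxes))
#' @rdname accessors
setMethod("instanceInfo", "InstanceSegmentation", function(x) x@instanceInfo)
#' @rdname accessors
setMethod("instanceMask", "InstanceSegmentation",
          function(x, id) x@labelMap == id)
#' @rdname accessors
setMethod("unionMask", "InstanceSegmentation", function(x) x@labelMap > 0L)
#' @rdname accessors
setMethod("featureTable", "FeatureTable", function(x) x@table)
#' @rdname accessors
setMethod("featureMatrix", "FeatureTable",
          function(x) as.matrix(x@table[featureNames()]))
#' @rdname accessors
setMethod("scalingState", "FeatureTable", function(x) x@scalingState)
#' @rdname accessors
setMethod("anomalyLabels", "AnomalyResult", function(x) x@labels)
#' @rdname accessors
setMethod("decisionValues", "AnomalyResult", function(x) x@decisionValues)
#' @rdname accessors
setMethod("bestParams", "AnomalyResult", function(x) x@bestParams)
#' @rdname accessors
setMethod("gridLog", "AnomalyResult", function(x) x@gridLog)
#' @rdname accessors
setMethod("sceneImage", "SceneTruth", function(x) x@image)
#' @rdname accessors
setMethod("sceneCounts", "SceneTruth", function(x) x@counts)
#' @rdname accessors
setMethod("anomalyIds", "SceneTruth", function(x) x@anomalyIds)

setMethod("show", "RGBImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RGBImage '%s': %d x %d, scale=%s, range [%.4g, %.4g]\n",
              object@id, d[1], d[2], object@scale,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "IndexMap", function(object) {
  cat(sprintf("IndexMap %s of '%s': %d x %d, range [%.4g, %.4g]\n",
              object@indexName, object@sourceId, nrow(object@values),
              ncol(object@values), min(object@values), max(object@values)))
})

setMethod("show", "PromptSet", function(object) {
  cat(sprintf("PromptSet for '%s': %d point prompt(s)\n",
              object@sourceId, nrow(object@points)))
})

setMethod("show", "InstanceSegmentation", function(object) {
  cat(sprintf("InstanceSegmentation of '%s': %d instance(s), %d x %d\n",
              object@sourceId, nrow(object@instanceInfo),
              nrow(object@labelMap), ncol(object@labelMap)))
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d seedling(s) x %d features (%s)\n",
              nrow(object@table), length(featureNames()),
              object@scalingState))
})

setMethod("show", "AnomalyResult", function(object) {
  cat(sprintf(
    "AnomalyResult: %d seedling(s), %d outlier(s); kernel=%s nu=%g gamma=%s; silhouette=%.3f\n",
    length(object@labels), sum(object@labels == -1L),
    object@bestParams$kernel, object@bestParams$nu,
    as.character(object@bestParams$gamma), object@silhouette))
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth '%s': %d plant(s), %d planted anomalies (stage %s)\n",
              object@image@id, object@counts, length(object@anomalyIds),
              object@params$config$stage))
})

setMethod("show", "SegmenterBackend", function(object) {
  cat(sprintf("SegmenterBackend '%s' (capabilities: point_prompt)\n",
              object@name))
})
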