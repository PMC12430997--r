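#' Run stage one: prompts and instance segmentation over a batch
#'
#' For every image: unit normalization, ExGR, multi-Otsu vegetation map,
#' connected-component point prompts, then the promptable segmenter.
#' Per-image artifacts (prompt CSV, label map, union mask, instance CSV)
#' and an effective-config echo are written under `outDir`. A failure on
#' one image is logged and isolated; the call errors only if every image
#' fails.
#'
#' @param images list of [RGBImage-class] objects, or character paths
#'   readable by [readRGBImage()].
#' @param outDir output directory.
#' @param backend a [SegmenterBackend-class] (default [fallbackBackend()]),
#'   or a function `(image_id) -> backend` for per-image backends (as with
#'   the oracle).
#' @param normalizeMode,nClasses,minArea,connectivity,center,mergeIoU
#'   stage-one parameters; see [normalizeImage()], [multiOtsu()],
#'   [componentsToPrompts()] and [segmentSeedlings()].
#' @return named list of [InstanceSegmentation-class], invisibly.
#' @export
runSegmentStage <- function(images, outDir, backend = fallbackBackend(),
                            normalizeMode = "unit", nClasses = 3L,
                            minArea = 20L, connectivity = 8L,
                            center = "bbox", mergeIoU = 0.5) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(images)) {
    if (!length(images)) stop("usage error: no input images")
    images <- lapply(images, readRGBImage)
  }
  if (!length(images)) stop("usage error: no input images")
  segs <- list(); failures <- character(0); logRows <- list()
  for (img in images) {
    id <- img@id
    res <- tryCatch({
      t0 <- proc.time()[["elapsed"]]
      norm <- normalizeImage(img, normalizeMode)
      idx <- exgr(norm)
      bm <- multiOtsu(idx, nClasses = nClasses)
      prompts <- componentsToPrompts(bm, minArea = minArea,
                                     connectivity = connectivity,
                                     center = center, sourceId = id)
      be <- if (is.function(backend)) backend(id) else backend
      seg <- segmentSeedlings(img, prompts, be, mergeIoU = mergeIoU)
      writePrompts(prompts, file.path(outDir, paste0(id, "_prompts.csv")))
      writeSegmentation(seg, outDir, prefix = id)
      logRows[[id]] <- data.frame(
        image_id = id, n_prompts = nInstances(prompts),
        n_instances = nInstances(seg))
      cat(sprintf("%s: %d prompts, %d instances, %.2fs\n", id,
                  nInstances(prompts), nInstances(seg),
                  proc.time()[["elapsed"]] - t0),
          file = file.path(outDir, "timings.log"), append = TRUE)
      seg
    }, error = function(e) {
      warning("image '", id, "' failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- c(failures, id) else segs[[id]] <- res
  }
  if (!length(segs))
    stop("all ", length(failures), " image(s) failed in stage one")
  writeCsvStable(do.call(rbind, logRows), file.path(outDir, "run_log.csv"))
  writeConfigEcho(outDir, list(
    stage = "segment", normalize_mode = normalizeMode,
    otsu_n_classes = nClasses, prompt_min_area = minArea,
    prompt_connectivity = connectivity, prompt_center = center,
    segmenter_backend = if (is.function(backend)) "per-image" else
      backend@name,
    merge_iou = mergeIoU))
  invisible(segs)
}

#' Run stage two: features and anomaly detection over a batch
#'
#' Builds the 15-feature table for every segmented seedling, pools the
#' rows across images, standardizes, runs the silhouette-guided one-class
#' SVM grid search, and writes: feature CSV, anomaly CSV (`image_id,
#' instance_id, label, decision_value`), per-feature Bhattacharyya CSV
#' (raw feature space), grid-log CSV, embedding CSV, a params JSON
#' (selected model, silhouette, seed) and overlay PNGs with outliers
#' outlined.
#'
#' @param segs named list of [InstanceSegmentation-class] (from
#'   [runSegmentStage()]).
#' @param images named list of the matching [RGBImage-class] objects.
#' @param outDir output directory.
#' @param glcm a [glcmConfig()].
#' @param grid an [ocsvmGrid()].
#' @param seed integer seed (recorded; also seeds the embedding).
#' @return list with `features` ([FeatureTable-class], raw),
#'   `result` ([AnomalyResult-class]), `bhattacharyya` (data.frame),
#'   `embedding` (matrix or `NULL`), invisibly.
#' @export
runHealthStage <- function(segs, images, outDir, glcm = glcmConfig(),
                           grid = ocsvmGrid(), seed = 1L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(names(images))) names(images) <-
      vapply(images, imageId, character(1))
  tabs <- list()
  for (id in names(segs)) {
    ft <- buildFeatureTable(segs[[id]], images[[id]], glcm = glcm)
    tab <- featureTable(ft)
    if (nrow(tab)) tab <- cbind(image_id = id, tab)
    tabs[[id]] <- tab
  }
  pooled <- do.call(rbind, tabs[vapply(tabs, nrow, integer(1)) > 0])
  if (is.null(pooled) || nrow(pooled) < 10L)
    stop("stage two refused: fewer than 10 segmented seedlings in the ",
         "batch (one-class SVM precondition)")
  rownames(pooled) <- NULL
  raw <- new("FeatureTable",
             table = transform(pooled[setdiff(names(pooled), "image_id")],
                               instance_id = seq_len(nrow(pooled))),
             scalingState = "raw", glcmConfig = glcm)
  std <- standardizeFeatures(raw)
  res <- fitOcsvm(std, space = grid, seed = seed)
  bh <- bhattacharyyaDistance(raw, anomalyLabels(res))
  emb <- suppressWarnings(embed2d(std, seed = seed))

  featOut <- cbind(pooled["image_id"], orig_instance_id = pooled$instance_id,
                   raw@table)
  writeCsvStable(featOut, file.path(outDir, "features.csv"))
  writeCsvStable(data.frame(image_id = pooled$image_id,
                            instance_id = pooled$instance_id,
                            label = anomalyLabels(res),
                            decision_value = decisionValues(res)),
                 file.path(outDir, "anomaly.csv"))
  writeCsvStable(bh, file.path(outDir, "bhattacharyya.csv"))
  writeCsvStable(gridLog(res), file.path(outDir, "grid_log.csv"))
  if (!is.null(emb))
    writeCsvStable(data.frame(image_id = pooled$image_id,
                              instance_id = pooled$instance_id,
                              dim1 = emb[, 1], dim2 = emb[, 2]),
                   file.path(outDir, "embedding.csv"))
  bp <- bestParams(res)
  jsonlite::write_json(
    list(kernel = bp$kernel, nu = bp$nu, gamma = as.character(bp$gamma),
         gamma_value = bp$gamma_value, degree = bp$degree,
         silhouette = res@silhouette, seed = seed,
         n_seedlings = nrow(pooled),
         n_outliers = sum(anomalyLabels(res) == -1L)),
    file.path(outDir, "params.json"), auto_unbox = TRUE, digits = NA)
  writeOverlays(segs, images, pooled, anomalyLabels(res), outDir)
  writeConfigEcho(outDir, list(stage = "health", glcm_levels = glcm$levels,
                               glcm_region = glcm$region, seed = seed))
  invisible(list(features = raw, result = res, bhattacharyya = bh,
                 embedding = emb))
}

# outline each outlier seedling in red on its source image
writeOverlays <- function(segs, images, pooled, labels, outDir) {
  pooled$label <- labels
  for (id in names(segs)) {
    img <- images[[id]]
    px <- if (img@scale == "uint8") img@pixels / 255 else img@pixels
    lm <- labelMap(segs[[id]])
    bad <- pooled$instance_id[pooled$image_id == id & pooled$label == -1L]
    for (k in bad) {
      m <- lm == k
      edge <- m & !(shiftLogical(m, 1, 0) & shiftLogical(m, -1, 0) &
                    shiftLogical(m, 0, 1) & shiftLogical(m, 0, -1))
      px[, , 1][edge] <- 1; px[, , 2][edge] <- 0; px[, , 3][edge] <- 0
    }
    png::writePNG(px, file.path(outDir, paste0(id, "_overlay.png")))
  }
}

shiftLogical <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Run the evaluation stage
#'
#' Pixel metrics and count regression for matched prediction/truth pairs;
#' writes `metrics.csv` and a `summary.json` (overall and per-stage mean
#' metrics plus the regression).
#'
#' @inheritParams evaluateBatch
#' @param outDir output directory.
#' @return the [evaluateBatch()] result, invisibly.
#' @export
runEvaluateStage <- function(preds, truths, outDir, counts = NULL,
                             stages = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ev <- evaluateBatch(preds, truths, counts = counts, stages = stages)
  writeCsvStable(ev$per_image, file.path(outDir, "metrics.csv"))
  jsonlite::write_json(list(summary = ev$summary,
                            regression = ev$regression),
                       file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeConfigEcho(outDir, list(stage = "evaluate"))
  invisible(ev)
}

#' Materialize the standard synthetic fixture set
#'
#' Writes `nSeeds` three-stage series (image PNG, 16-bit label PNG, truth
#' JSON each) under `outDir`.
#'
#' @param outDir output directory.
#' @param nSeeds number of series (seeds `1..nSeeds`).
#' @param ... overrides forwarded to [sceneConfig()].
#' @return `outDir`, invisibly.
#' @export
writeFixtures <- function(outDir, nSeeds = 3L, ...) {
  for (s in seq_len(nSeeds)) {
    series <- stageSeries(seed = s, ...)
    for (truth in series) writeScene(truth, outDir)
  }
  writeConfigEcho(outDir, list(stage = "fixtures", n_seeds = nSeeds))
  invisible(outDir)
}

writeConfigEcho <- function(outDir, cfg) {
  cfg$package_version <- pkgVersionString()
  jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
}
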