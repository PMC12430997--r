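#' Classical region-growing fallback backend
#'
#' A self-contained point-promptable segmenter that needs no model
#' checkpoint: for a prompt point it flood-fills (8-connected) the pixels
#' whose ExGR value reaches the image's multi-Otsu vegetation threshold,
#' clipped to a configurable maximum radius around the seed. If the seed
#' pixel itself is below threshold, the nearest above-threshold pixel
#' within 5 px is used instead; failing that, an empty mask with score 0 is
#' returned. The score is the region's mean ExGR rescaled to `[0, 1]` by
#' the image's ExGR range.
#'
#' @param nClasses Otsu classes used for the vegetation threshold
#'   (default 3).
#' @param maxRadius maximum growth radius in px (default 30).
#' @param seedSearch radius in px for rescuing a below-threshold seed
#'   (default 5).
#' @return A `FallbackBackend`.
#' @export
fallbackBackend <- function(nClasses = 3L, maxRadius = 30, seedSearch = 5) {
  new("FallbackBackend", name = "fallback",
      config = list(nClasses = as.integer(nClasses), maxRadius = maxRadius,
                    seedSearch = seedSearch),
      cache = new.env(parent = emptyenv()))
}

# per-image ExGR map + vegetation threshold, memoized on image id
fallbackContext <- function(backend, img) {
  key <- img@id
  if (!is.null(backend@cache[[key]])) return(backend@cache[[key]])
  idx <- exgr(normalizeImage(img, "unit"))
  # degrade gracefully on low-diversity maps (e.g. flat test scenes)
  nc <- min(backend@config$nClasses,
            max(2L, length(unique(as.vector(idx@values))) - 1L))
  bm <- multiOtsu(idx, nClasses = nc)
  ctx <- list(values = idx@values,
              thr = bm@thresholds[length(bm@thresholds)],
              rng = range(idx@values))
  backend@cache[[key]] <- ctx
  ctx
}

#' Region-grow one mask from a seed point
#'
#' The fallback backend's core operation, exposed for direct use and
#' testing. Coordinates are 0-based `(row, col)`.
#'
#' @param img an [RGBImage-class].
#' @param point numeric `(row, col)` seed, 0-based.
#' @param nClasses,maxRadius,seedSearch see [fallbackBackend()].
#' @return list with `mask` (logical `H x W`) and `score` in `[0, 1]`.
#' @export
fallbackSegment <- function(img, point, nClasses = 3L, maxRadius = 30,
                            seedSearch = 5) {
  be <- fallbackBackend(nClasses, maxRadius, seedSearch)
  out <- proposeMasks(be, img, point)
  list(mask = out$masks[[1]], score = out$scores[1])
}

#' @rdname proposeMasks
setMethod("proposeMasks", "FallbackBackend", function(backend, img, point) {
  ctx <- fallbackContext(backend, img)
  H <- nrow(ctx$values); W <- ncol(ctx$values)
  r0 <- round(point[1]) + 1L; c0 <- round(point[2]) + 1L
  r0 <- min(max(r0, 1L), H); c0 <- min(max(c0, 1L), W)
  empty <- list(masks = list(matrix(FALSE, H, W)), scores = 0)
  if (ctx$values[r0, c0] < ctx$thr) {
    # rescue: nearest above-threshold pixel within seedSearch px
    s <- ceiling(backend@config$seedSearch)
    rr <- max(1L, r0 - s):min(H, r0 + s)
    cc <- max(1L, c0 - s):min(W, c0 + s)
    sub <- ctx$values[rr, cc, drop = FALSE] >= ctx$thr
    if (!any(sub)) return(empty)
    cand <- which(sub, arr.ind = TRUE)
    d2 <- (rr[cand[, 1]] - r0)^2 + (cc[cand[, 2]] - c0)^2
    ok <- d2 <= backend@config$seedSearch^2
    if (!any(ok)) return(empty)
    j <- which(ok)[which.min(d2[ok])]
    r0 <- rr[cand[j, 1]]; c0 <- cc[cand[j, 2]]
  }
  # window clipped to max radius; flood fill the thresholded map
  rad <- ceiling(backend@config$maxRadius)
  rr <- max(1L, r0 - rad):min(H, r0 + rad)
  cc <- max(1L, c0 - rad):min(W, c0 + rad)
  win <- ctx$values[rr, cc, drop = FALSE] >= ctx$thr
  dr <- outer(rr - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c0)
  win <- win & (dr^2 + dc^2 <= backend@config$maxRadius^2)
  lab <- labelComponents(win, 8L)
  seedLab <- lab[match(r0, rr), match(c0, cc)]
  if (seedLab == 0L) return(empty)
  mask <- matrix(FALSE, H, W)
  mask[rr, cc][lab == seedLab] <- TRUE
  span <- diff(ctx$rng)
  score <- if (span > 0)
    (mean(ctx$values[mask]) - ctx$rng[1]) / span else 1
  list(masks = list(mask), scores = min(max(score, 0), 1))
})

#' Ground-truth oracle backend for synthetic scenes
#'
#' Returns, for a prompt point, the ground-truth instance mask containing
#' the point (or the nearest instance within 2 px) with score 1, and an
#' empty mask with score 0 for background points. Enables pixel-exact
#' end-to-end tests of every non-segmenter stage.
#'
#' @param truth a [SceneTruth-class].
#' @return An `OracleBackend`.
#' @export
oracleBackend <- function(truth) {
  new("OracleBackend", name = "oracle", truth = truth)
}

#' @rdname proposeMasks
setMethod("proposeMasks", "OracleBackend", function(backend, img, point) {
  lm <- backend@truth@labelMap
  H <- nrow(lm); W <- ncol(lm)
  r0 <- min(max(round(point[1]) + 1L, 1L), H)
  c0 <- min(max(round(point[2]) + 1L, 1L), W)
  lab <- lm[r0, c0]
  if (lab == 0L) {
    rr <- max(1L, r0 - 2L):min(H, r0 + 2L)
    cc <- max(1L, c0 - 2L):min(W, c0 + 2L)
    sub <- lm[rr, cc, drop = FALSE]
    cand <- which(sub > 0, arr.ind = TRUE)
    if (nrow(cand)) {
      d2 <- (rr[cand[, 1]] - r0)^2 + (cc[cand[, 2]] - c0)^2
      ok <- d2 <= 4
      if (any(ok)) lab <- sub[cand[which(ok)[which.min(d2[ok])], , drop = FALSE]]
    }
  }
  if (lab == 0L)
    return(list(masks = list(matrix(FALSE, H, W)), scores = 0))
  list(masks = list(lm == lab), scores = 1)
})

#' Adapter for an external promptable foundation segmenter
#'
#' Wraps a pretrained promptable segmentation model (e.g. a ViT-H
#' checkpoint) in the [SegmenterBackend-class] contract. The constructor
#' validates the checkpoint; inference itself is delegated to a
#' user-supplied `predictor` function (signature
#' `function(pixels, point)` returning `list(masks =, scores =)`), since
#' the model runtime is an optional external dependency. Querying the
#' backend without a predictor raises a configuration error naming
#' [fallbackBackend()] as the offline alternative.
#'
#' @param checkpointPath path to the model checkpoint file.
#' @param modelType model identifier (default `"vit_h"`).
#' @param predictor optional inference function as described above.
#' @return A `FoundationBackend`.
#' @export
foundationAdapter <- function(checkpointPath, modelType = "vit_h",
                              predictor = NULL) {
  if (!is.character(checkpointPath) || !file.exists(checkpointPath))
    stop("configuration error: segmenter checkpoint not found: ",
         checkpointPath,
         " (use fallbackBackend() for checkpoint-free segmentation)")
  new("FoundationBackend", name = paste0("foundation:", modelType),
      checkpoint = checkpointPath, modelType = modelType,
      predictor = predictor)
}

#' @rdname proposeMasks
setMethod("proposeMasks", "FoundationBackend", function(backend, img, point) {
  if (is.null(backend@predictor))
    stop("configuration error: no predictor hooked up for the foundation ",
         "backend; supply one to foundationAdapter() or use ",
         "fallbackBackend()")
  out <- backend@predictor(img@pixels, point)
  stopifnot(is.list(out$masks), length(out$masks) == length(out$scores))
  out
})

maskIoU <- function(a, b) {
  i <- sum(a & b)
  u <- sum(a | b)
  if (u == 0) 0 else i / u
}

#' Segment seedlings from point prompts
#'
#' Queries the backend once per prompt point, keeps one candidate mask per
#' prompt (the highest-scoring one, or the smallest containing the prompt
#' under `multimaskPolicy = "smallest"`), drops masks that do not contain
#' their prompt within 1 px, then resolves overlaps: masks with pairwise
#' IoU above `mergeIoU` are merged into one instance (duplicate prompts on
#' one plant collapse rather than split), and remaining contested pixels go
#' to the instance whose prompt point is nearer. Instances are renumbered
#' consecutively in prompt order.
#'
#' @param img an [RGBImage-class].
#' @param prompts a [PromptSet-class] (may be empty).
#' @param backend a [SegmenterBackend-class].
#' @param mergeIoU IoU above which two masks are considered duplicates of
#'   one plant and merged (default 0.5).
#' @param multimaskPolicy `"best"` (highest backend score) or `"smallest"`.
#' @return An [InstanceSegmentation-class].
#' @export
segmentSeedlings <- function(img, prompts, backend, mergeIoU = 0.5,
                             multimaskPolicy = c("best", "smallest")) {
  multimaskPolicy <- match.arg(multimaskPolicy)
  hw <- pixdim(img)
  n <- nrow(prompts@points)
  kept <- list(); keptScore <- numeric(0); keptPt <- NULL
  for (i in seq_len(n)) {
    pt <- prompts@points[i, ]
    out <- tryCatch(proposeMasks(backend, img, pt), error = function(e) {
      warning("backend failed on prompt ", i, ": ", conditionMessage(e),
              "; prompt skipped")
      NULL
    })
    if (is.null(out) || !length(out$masks)) next
    j <- if (multimaskPolicy == "best") {
      which.max(out$scores)
    } else {
      areas <- vapply(out$masks, sum, numeric(1))
      contains <- vapply(out$masks, maskHasPointNear, logical(1), pt)
      if (any(contains)) which(contains)[which.min(areas[contains])]
      else which.max(out$scores)
    }
    m <- out$masks[[j]]
    if (!any(m)) next
    if (!maskHasPointNear(m, pt)) next  # prompt-containment rule (1 px)
    kept[[length(kept) + 1L]] <- m
    keptScore <- c(keptScore, out$scores[j])
    keptPt <- rbind(keptPt, pt)
  }
  k <- length(kept)
  if (k == 0L) {
    return(new("InstanceSegmentation",
               labelMap = matrix(0L, hw[1], hw[2]),
               instanceInfo = data.frame(instance_id = integer(0),
                                         prompt_row = numeric(0),
                                         prompt_col = numeric(0),
                                         score = numeric(0),
                                         area_px = integer(0)),
               sourceId = img@id))
  }
  # merge duplicates: union-find over pairs with IoU > mergeIoU
  parent <- seq_len(k)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  if (k > 1) for (a in 1:(k - 1)) for (b in (a + 1):k) {
    if (maskIoU(kept[[a]], kept[[b]]) > mergeIoU) {
      ra <- findRoot(a); rb <- findRoot(b)
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(k), findRoot, integer(1))
  groups <- split(seq_len(k), roots)
  groups <- groups[order(vapply(groups, min, integer(1)))]  # prompt order
  masks <- lapply(groups, function(g) Reduce(`|`, kept[g]))
  gpts <- t(vapply(groups, function(g) keptPt[min(g), ], numeric(2)))
  gscore <- vapply(groups, function(g) max(keptScore[g]), numeric(1))
  # contested pixels -> nearer prompt point
  lm <- matrix(0L, hw[1], hw[2])
  owner <- matrix(Inf, hw[1], hw[2])
  for (g in seq_along(masks)) {
    idx <- which(masks[[g]])
    r <- (idx - 1L) %% hw[1]; c <- (idx - 1L) %/% hw[1]
    d2 <- (r - gpts[g, 1])^2 + (c - gpts[g, 2])^2
    take <- d2 < owner[idx]
    lm[idx[take]] <- g
    owner[idx[take]] <- d2[take]
  }
  # renumber in case a group lost all its pixels
  present <- sort(unique(lm[lm > 0]))
  relab <- match(seq_along(masks), present)
  lm[lm > 0] <- match(lm[lm > 0], present)
  keep <- which(!is.na(relab))
  info <- data.frame(instance_id = seq_along(keep),
                     prompt_row = gpts[keep, 1], prompt_col = gpts[keep, 2],
                     score = gscore[keep],
                     area_px = as.integer(tabulate(lm[lm > 0],
                                                   length(keep))))
  new("InstanceSegmentation", labelMap = lm, instanceInfo = info,
      sourceId = img@id)
}

# prompt containment within Chebyshev distance 1 of the rounded point
maskHasPointNear <- function(mask, pt) {
  H <- nrow(mask); W <- ncol(mask)
  r0 <- min(max(round(pt[1]) + 1L, 1L), H)
  c0 <- min(max(round(pt[2]) + 1L, 1L), W)
  rr <- max(1L, r0 - 1L):min(H, r0 + 1L)
  cc <- max(1L, c0 - 1L):min(W, c0 + 1L)
  any(mask[rr, cc])
}

#' Write instance-segmentation artifacts
#'
#' Writes the label map as a losslessly encoded PNG (see
#' [readLabelPNG()]), the union mask as 8-bit PNG, the instance table as
#' CSV and, optionally, the per-instance binary masks as a paged TIFF.
#'
#' @param seg an [InstanceSegmentation-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (defaults to the source id).
#' @param masksTiff also write `<prefix>_masks.tif`, one page per
#'   instance (default `FALSE`; the label map already carries the same
#'   information).
#' @return character vector of paths written, invisibly.
#' @export
writeSegmentation <- function(seg, dir, prefix = NULL, masksTiff = FALSE) {
  if (is.null(prefix)) prefix <- seg@sourceId
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pLab <- file.path(dir, paste0(prefix, "_labels.png"))
  pUni <- file.path(dir, paste0(prefix, "_mask.png"))
  pCsv <- file.path(dir, paste0(prefix, "_instances.csv"))
  writeLabelPNG(seg@labelMap, pLab)
  png::writePNG((seg@labelMap > 0) * 1, pUni)
  writeCsvStable(seg@instanceInfo, pCsv)
  paths <- c(pLab, pUni, pCsv)
  if (masksTiff && nInstances(seg) > 0) {
    pTif <- file.path(dir, paste0(prefix, "_masks.tif"))
    pages <- lapply(seq_len(nInstances(seg)),
                    function(k) (seg@labelMap == k) * 1)
    invisible(tiff::writeTIFF(pages, pTif, bits.per.sample = 8L))
    paths <- c(paths, pTif)
  }
  invisible(paths)
}
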