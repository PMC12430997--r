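#' Multi-Otsu thresholding of an index map
#'
#' Bins the real-valued index into `nbins` equal-width bins over its
#' observed range and finds the `nClasses - 1` thresholds maximizing the
#' between-class variance of the histogram (the multi-level extension of
#' Otsu's criterion). The returned mask selects the most-vegetated class,
#' `index >= max(thresholds)`. Default `nClasses = 3` reflects the typical
#' paddy histogram: background, water/soil mix, vegetation.
#'
#' @param index an [IndexMap-class] (normally ExGR).
#' @param nClasses number of classes, 2, 3 or 4.
#' @param nbins number of histogram bins (default 256, mirroring 8-bit
#'   practice).
#' @return A [BinaryMap-class]; `thresholds` holds the bin-edge thresholds
#'   in index units, ascending.
#' @export
multiOtsu <- function(index, nClasses = 3L, nbins = 256L) {
  stopifnot(nClasses %in% 2:4)
  v <- as.vector(index@values)
  if (length(unique(v)) < nClasses)
    stop("degenerate input: fewer than ", nClasses,
         " distinct index values; try nClasses = 2")
  lo <- min(v); hi <- max(v)
  width <- (hi - lo) / nbins
  bin <- pmin(nbins, floor((v - lo) / width) + 1L)
  counts <- tabulate(bin, nbins)
  cuts <- otsuSplit(counts, nClasses - 1L)
  thr <- lo + cuts * width  # upper edge of the last bin of each lower class
  mask <- matrix(index@values >= thr[length(thr)], nrow(index@values))
  new("BinaryMap", mask = mask, thresholds = thr,
      nClasses = as.integer(nClasses))
}

# Maximize between-class variance sum(w_k * mu_k^2) over k-1 histogram cut
# points; returns cut positions (number of bins below each cut), ascending.
otsuSplit <- function(counts, nthr) {
  n <- length(counts)
  p <- counts / sum(counts)
  i <- seq_len(n)
  cw <- cumsum(p)              # cumulative weight up to bin t
  cm <- cumsum(p * i)          # cumulative first moment
  # classScore(a, b): w * mu^2 for the class spanning bins (a, b];
  # vectorized in either argument
  classScore <- function(a, b) {
    cwa <- ifelse(a > 0, cw[pmax(a, 1L)], 0)
    cma <- ifelse(a > 0, cm[pmax(a, 1L)], 0)
    w <- cw[b] - cwa
    m <- cm[b] - cma
    ifelse(w > 0, m^2 / w, 0)
  }
  best <- -Inf; bestCut <- NULL
  if (nthr == 1L) {
    t1 <- seq_len(n - 1L)
    sc <- classScore(0L, t1) + classScore(t1, n)
    k <- which.max(sc); best <- sc[k]; bestCut <- k
  } else if (nthr == 2L) {
    for (t1 in seq_len(n - 2L)) {
      t2 <- seq.int(t1 + 1L, n - 1L)
      sc <- classScore(0L, t1) + classScore(t1, t2) + classScore(t2, n)
      k <- which.max(sc)
      if (sc[k] > best) { best <- sc[k]; bestCut <- c(t1, t2[k]) }
    }
  } else {
    for (t1 in seq_len(n - 3L)) {
      s1 <- classScore(0L, t1)
      for (t2 in seq.int(t1 + 1L, n - 2L)) {
        t3 <- seq.int(t2 + 1L, n - 1L)
        sc <- s1 + classScore(t1, t2) + classScore(t2, t3) + classScore(t3, n)
        k <- which.max(sc)
        if (sc[k] > best) { best <- sc[k]; bestCut <- c(t1, t2, t3[k]) }
      }
    }
  }
  bestCut
}

#' Label connected components of a binary mask
#'
#' 4- or 8-connectivity. 8-connectivity is obtained by merging 4-connected
#' labels that touch diagonally.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels (0 = background, 1..K components).
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  lab4 <- EBImage::bwlabel(mask * 1L)
  lab4 <- matrix(as.integer(lab4), nrow(mask))
  k <- max(lab4)
  if (connectivity == 4L || k <= 1L) return(lab4)
  # union-find over diagonally adjacent 4-connected labels
  parent <- seq_len(k)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  H <- nrow(lab4); W <- ncol(lab4)
  a1 <- lab4[-H, -W]; b1 <- lab4[-1, -1]   # down-right diagonal
  a2 <- lab4[-H, -1]; b2 <- lab4[-1, -W]   # down-left diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- unique(pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                        pairs[, 1] != pairs[, 2], , drop = FALSE])
  for (r in seq_len(nrow(pairs))) {
    ra <- findRoot(pairs[r, 1]); rb <- findRoot(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(k), findRoot, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab4
  out[out > 0] <- relabel[out[out > 0]]
  out
}

#' Turn a binary vegetation map into point prompts
#'
#' Labels connected components, discards those smaller than `minArea`
#' pixels, and emits each survivor's tight bounding box together with the
#' box's geometric center — the hint point handed to the promptable
#' segmenter. Components are ordered by `(row_min, col_min)` for
#' determinism. Boxes are half-open on their max edges in 0-based
#' `(row, col)` coordinates.
#'
#' @param bmap a [BinaryMap-class].
#' @param minArea minimum component area in pixels (default 20, suppressing
#'   single-pixel noise at typical UAV resolutions).
#' @param connectivity 4 or 8 (default 8).
#' @param center `"bbox"` (geometric center of the bounding box, the
#'   pipeline default) or `"centroid"` (component centroid).
#' @param sourceId id recorded on the prompt set.
#' @return A [PromptSet-class]; empty mask yields zero prompts (not an
#'   error).
#' @export
componentsToPrompts <- function(bmap, minArea = 20L, connectivity = 8L,
                                center = c("bbox", "centroid"),
                                sourceId = "") {
  center <- match.arg(center)
  lab <- labelComponents(bmap@mask, connectivity)
  k <- max(lab)
  boxes <- matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("row_min", "col_min",
                                          "row_max", "col_max")))
  pts <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  ids <- integer(0)
  if (k > 0) {
    idx <- which(lab > 0, arr.ind = TRUE)
    lv <- lab[lab > 0]
    area <- tabulate(lv, k)
    keep <- which(area >= minArea)
    if (length(keep)) {
      rmin <- tapply(idx[, 1], lv, min)[as.character(keep)] - 1L
      rmax <- tapply(idx[, 1], lv, max)[as.character(keep)]
      cmin <- tapply(idx[, 2], lv, min)[as.character(keep)] - 1L
      cmax <- tapply(idx[, 2], lv, max)[as.character(keep)]
      ord <- order(rmin, cmin)
      boxes <- cbind(row_min = rmin, col_min = cmin,
                     row_max = rmax, col_max = cmax)[ord, , drop = FALSE]
      ids <- keep[ord]
      if (center == "bbox") {
        # midpoint of the inclusive pixel span (boxes are half-open on max)
        pts <- cbind(row = (boxes[, 1] + boxes[, 3] - 1) / 2,
                     col = (boxes[, 2] + boxes[, 4] - 1) / 2)
      } else {
        cr <- tapply(idx[, 1] - 1L, lv, mean)[as.character(keep)]
        cc <- tapply(idx[, 2] - 1L, lv, mean)[as.character(keep)]
        pts <- cbind(row = cr, col = cc)[ord, , drop = FALSE]
      }
      rownames(boxes) <- rownames(pts) <- NULL
    }
  }
  new("PromptSet", boxes = boxes, points = pts,
      componentIds = as.integer(ids), sourceId = sourceId)
}

#' Serialize a prompt set
#'
#' CSV columns: `component_id, row_min, col_min, row_max, col_max,
#' point_row, point_col`. A `.json` path instead writes the prompt file
#' consumed by the segmentation stage (`source_id`, `boxes`, `points`,
#' `component_ids`).
#'
#' @param prompts a [PromptSet-class].
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
writePrompts <- function(prompts, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(source_id = prompts@sourceId,
           boxes = unname(apply(prompts@boxes, 1, as.numeric,
                                simplify = FALSE)),
           points = unname(apply(prompts@points, 1, as.numeric,
                                 simplify = FALSE)),
           component_ids = prompts@componentIds),
      path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  df <- data.frame(component_id = prompts@componentIds,
                   row_min = prompts@boxes[, 1], col_min = prompts@boxes[, 2],
                   row_max = prompts@boxes[, 3], col_max = prompts@boxes[, 4],
                   point_row = prompts@points[, 1],
                   point_col = prompts@points[, 2])
  writeCsvStable(df, path)
}

#' Read a JSON prompt file
#'
#' @param path a file written by [writePrompts()] with a `.json` path.
#' @return A [PromptSet-class].
#' @export
readPrompts <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  asMat <- function(x, k) {
    if (is.matrix(x)) x
    else if (length(x)) matrix(unlist(x), ncol = k, byrow = TRUE)
    else matrix(numeric(0), 0, k)
  }
  boxes <- asMat(j$boxes, 4)
  pts <- asMat(j$points, 2)
  new("PromptSet", boxes = boxes, points = pts,
      componentIds = as.integer(j$component_ids), sourceId = j$source_id)
}
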