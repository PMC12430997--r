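#' Pixel-level confusion counts
#'
#' Foreground = seedling. TP: seedling pixels predicted seedling; TN:
#' background predicted background; FP: background predicted seedling;
#' FN: seedling pixels missed.
#'
#' @param pred,truth logical matrices of equal dimensions.
#' @return named list `tp`, `fp`, `fn`, `tn` (integers summing to `H*W`).
#' @export
pixelConfusion <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("prediction and truth masks differ in shape")
  list(tp = sum(pred & truth), fp = sum(pred & !truth),
       fn = sum(!pred & truth), tn = sum(!pred & !truth))
}

#' Dice, IoU and false-positive rate from a confusion
#'
#' `dice = 2 TP / (2 TP + FP + FN)`, `iou = TP / (TP + FP + FN)`,
#' `fpr = FP / (FP + TN)`. Conventions for degenerate images: when
#' prediction and truth are both empty (`TP + FP + FN = 0`) dice and iou
#' are 1 and flagged; when there are no true background pixels
#' (`FP + TN = 0`) fpr is `NA` and flagged.
#'
#' @param conf a [pixelConfusion()] list.
#' @return named list `dice`, `iou`, `fpr`, `flag_empty`, `flag_fpr`.
#' @export
diceIouFpr <- function(conf) {
  denomSeg <- 2 * conf$tp + conf$fp + conf$fn
  empty <- denomSeg == 0
  dice <- if (empty) 1 else 2 * conf$tp / denomSeg
  iou <- if (empty) 1 else conf$tp / (conf$tp + conf$fp + conf$fn)
  noBg <- (conf$fp + conf$tn) == 0
  fpr <- if (noBg) NA_real_ else conf$fp / (conf$fp + conf$tn)
  list(dice = dice, iou = iou, fpr = fpr,
       flag_empty = empty, flag_fpr = noBg)
}

#' Batch means of the segmentation metrics
#'
#' Unweighted mean of the per-image metrics (mDice, mIoU, mFPR).
#' Flagged-undefined entries are excluded from the corresponding mean and
#' the exclusion count is reported.
#'
#' @param confusions list of [pixelConfusion()] results (one per image).
#' @return named list `mDice`, `mIoU`, `mFPR`, `n`, `n_excluded_fpr`,
#'   `n_flag_empty`.
#' @export
meanMetrics <- function(confusions) {
  if (!length(confusions)) stop("empty batch: no images to average")
  per <- lapply(confusions, diceIouFpr)
  fprs <- vapply(per, `[[`, numeric(1), "fpr")
  list(mDice = mean(vapply(per, `[[`, numeric(1), "dice")),
       mIoU = mean(vapply(per, `[[`, numeric(1), "iou")),
       mFPR = if (all(is.na(fprs))) NA_real_ else mean(fprs, na.rm = TRUE),
       n = length(per),
       n_excluded_fpr = sum(is.na(fprs)),
       n_flag_empty = sum(vapply(per, `[[`, logical(1), "flag_empty")))
}

#' Seedling-count regression
#'
#' Ordinary least squares of predicted counts on true counts, with the
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot` — the
#' agreement statistic used for count validation.
#'
#' @param pairs data.frame with columns `predicted` and `true` (>= 3 rows,
#'   nonzero variance in `true`).
#' @return named list `slope`, `intercept`, `r2`, `n`.
#' @export
countRegression <- function(pairs) {
  stopifnot(all(c("predicted", "true") %in% names(pairs)))
  if (nrow(pairs) < 3L) stop("need at least 3 (predicted, true) pairs")
  if (var(pairs$true) == 0)
    stop("R^2 undefined: true counts are constant")
  fit <- lm(predicted ~ true, data = pairs)
  pred <- predict(fit)
  ssRes <- sum((pairs$predicted - pred)^2)
  ssTot <- sum((pairs$predicted - mean(pairs$predicted))^2)
  r2 <- if (ssTot == 0) { if (ssRes == 0) 1 else -Inf } else 1 - ssRes / ssTot
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = r2, n = nrow(pairs))
}

#' Batch evaluation report
#'
#' Computes per-image metrics and the count regression for matched
#' prediction/truth pairs, optionally grouped into user-supplied stages
#' (mirroring stage-wise segmentation summaries).
#'
#' @param preds named list of predicted label maps (integer matrices) or
#'   logical union masks.
#' @param truths named list of ground-truth masks (logical or integer
#'   matrices; nonzero = seedling), names matched against `preds`.
#' @param counts optional data.frame `image_id`, `true_count`; predicted
#'   counts are the number of distinct instance labels per prediction.
#' @param stages optional named character vector mapping image id to stage.
#' @return list with `per_image` data.frame, `summary` (overall and
#'   per-stage mean metrics), and `regression` (or `NULL` without counts).
#' @export
evaluateBatch <- function(preds, truths, counts = NULL, stages = NULL) {
  ids <- intersect(names(preds), names(truths))
  skipped <- setdiff(union(names(preds), names(truths)), ids)
  if (length(skipped))
    warning("unmatched ids skipped: ", paste(skipped, collapse = ", "))
  if (!length(ids)) stop("no matched prediction/truth ids")
  rows <- lapply(ids, function(id) {
    p <- preds[[id]]; tmask <- truths[[id]] > 0
    conf <- pixelConfusion(p > 0, tmask)
    m <- diceIouFpr(conf)
    nPred <- length(unique(p[p > 0]))
    data.frame(image_id = id, dice = m$dice, iou = m$iou, fpr = m$fpr,
               flag_empty = m$flag_empty, pred_count = nPred)
  })
  per <- do.call(rbind, rows)
  confs <- lapply(ids, function(id)
    pixelConfusion(preds[[id]] > 0, truths[[id]] > 0))
  summary <- list(overall = meanMetrics(confs))
  if (!is.null(stages)) {
    for (st in unique(stages[ids])) {
      sel <- ids[stages[ids] == st]
      summary[[st]] <- meanMetrics(confs[match(sel, ids)])
    }
  }
  reg <- NULL
  if (!is.null(counts)) {
    merged <- merge(per, counts, by = "image_id")
    if (nrow(merged) >= 3L) {
      reg <- countRegression(data.frame(predicted = merged$pred_count,
                                        true = merged$true_count))
      per <- merge(per, counts, by = "image_id", all.x = TRUE)
    }
  }
  list(per_image = per, summary = summary, regression = reg)
}
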