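#' Standardize a feature table
#'
#' Per-column z-score using the column mean and population standard
#' deviation (divide by `n`). Zero-variance columns pass through unchanged
#' and are flagged in `flag_constant`; the per-feature `(mean, sd)` pair is
#' stored for inverse mapping. This is the space the one-class SVM and the
#' silhouette see.
#'
#' @param ft a raw [FeatureTable-class] with at least 2 rows.
#' @return A standardized [FeatureTable-class].
#' @export
standardizeFeatures <- function(ft) {
  stopifnot(scalingState(ft) == "raw")
  if (nrow(ft@table) < 2L)
    stop("insufficient data: need at least 2 seedlings to standardize")
  X <- featureMatrix(ft)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2, mu)^2))
  tab <- ft@table
  flat <- sdv < 1e-12
  for (j in seq_along(featureNames())) {
    nm <- featureNames()[j]
    if (!flat[j]) tab[[nm]] <- (tab[[nm]] - mu[j]) / sdv[j]
  }
  if (any(flat)) tab$flag_constant <- tab$flag_constant | TRUE
  new("FeatureTable", table = tab, scalingState = "standardized",
      center = mu, scale = ifelse(flat, 1, sdv), glcmConfig = ft@glcmConfig)
}

#' Default one-class-SVM grid
#'
#' All three kernels, `nu` in `{0.01, 0.05, 0.1}` and `gamma` in
#' `{0.01, 0.1, auto, scale}` (`auto` = `1/d`; `scale` =
#' `1/(d * var(X))` with the overall matrix variance). `gamma` has no
#' effect for the linear kernel; those duplicate combinations are
#' collapsed and noted in the grid log. Polynomial degree is fixed at 3.
#'
#' @param kernels subset of `c("linear", "rbf", "polynomial")`.
#' @param nus numeric vector in `(0, 1)`.
#' @param gammas list mixing positive reals and the strings `"auto"`,
#'   `"scale"`.
#' @param degree polynomial degree.
#' @return list describing the search space.
#' @export
ocsvmGrid <- function(kernels = c("linear", "rbf", "polynomial"),
                      nus = c(0.01, 0.05, 0.1),
                      gammas = list(0.01, 0.1, "auto", "scale"),
                      degree = 3L) {
  stopifnot(all(kernels %in% c("linear", "rbf", "polynomial")),
            all(unlist(lapply(nus, function(x) x > 0 && x < 1))))
  list(kernels = kernels, nus = nus, gammas = gammas,
       degree = as.integer(degree))
}

resolveGamma <- function(gamma, X) {
  if (identical(gamma, "auto")) return(1 / ncol(X))
  if (identical(gamma, "scale")) {
    v <- var2(as.vector(X))
    return(if (v > 0) 1 / (ncol(X) * v) else 1 / ncol(X))
  }
  as.numeric(gamma)
}

#' Fit a one-class SVM with silhouette-guided grid search
#'
#' For every `(kernel, nu, gamma)` combination a one-class SVM is fit on
#' all rows of the standardized feature table and every seedling is
#' labelled inlier (`+1`) or outlier (`-1`). The silhouette score of that
#' two-group partition (Euclidean distance in the standardized feature
#' space) ranks the combinations; one-class outcomes score `-Inf` so they
#' can never win. Ties break by kernel order as listed, then ascending
#' `nu`, then gamma order as listed. The full grid log is retained.
#'
#' @param ft a standardized [FeatureTable-class] with `n >= 10` rows.
#' @param space an [ocsvmGrid()] search space.
#' @param seed integer seed recorded in the result (the fit itself is
#'   deterministic).
#' @return An [AnomalyResult-class].
#' @export
fitOcsvm <- function(ft, space = ocsvmGrid(), seed = 1L) {
  stopifnot(scalingState(ft) == "standardized")
  X <- featureMatrix(ft)
  n <- nrow(X)
  if (n < 10L) stop("insufficient data: one-class SVM needs n >= 10")
  D <- dist(X)
  combos <- list(); logRows <- list()
  best <- NULL; bestSil <- -Inf
  seen <- character(0)
  for (kern in space$kernels) for (nu in space$nus)
    for (g in space$gammas) {
      gval <- resolveGamma(g, X)
      key <- if (kern == "linear") sprintf("linear|%g", nu)
             else sprintf("%s|%g|%.12g", kern, nu, gval)
      dup <- key %in% seen
      seen <- c(seen, key)
      if (dup) {
        logRows[[length(logRows) + 1L]] <- data.frame(
          kernel = kern, nu = nu, gamma = as.character(g),
          silhouette = NA_real_, n_outliers = NA_integer_,
          note = "duplicate (gamma inert for linear kernel)")
        next
      }
      fit <- e1071::svm(X, y = NULL, type = "one-classification",
                        kernel = if (kern == "rbf") "radial" else kern,
                        nu = nu, gamma = gval, degree = space$degree,
                        scale = FALSE)
      dv <- as.numeric(attr(predict(fit, X, decision.values = TRUE),
                            "decision.values"))
      labs <- ifelse(dv >= 0, 1L, -1L)
      nOut <- sum(labs == -1L)
      # a valid one-class solution obeys the nu-property (at most ~nu*n
      # strictly-negative decision values); a fit exceeding it has
      # collapsed (rho ~ 0) and is ineligible for selection
      degen <- if (nOut == 0L || nOut == n) "one-class"
               else if (nOut / n > nu + 0.05) "collapsed (nu-bound violated)"
               else ""
      sil <- if (nzchar(degen)) -Inf else silhouetteFromDist(labs, D)
      logRows[[length(logRows) + 1L]] <- data.frame(
        kernel = kern, nu = nu, gamma = as.character(g),
        silhouette = ifelse(is.finite(sil), sil, NA_real_),
        n_outliers = nOut, note = degen)
      if (sil > bestSil) {
        bestSil <- sil
        best <- list(kernel = kern, nu = nu, gamma = g, gamma_value = gval,
                     degree = space$degree, labels = labs, dv = dv)
      }
    }
  if (is.null(best))
    stop("no separation: every grid combination produced a single class; ",
         "try a larger nu")
  new("AnomalyResult",
      instanceIds = as.integer(ft@table$instance_id),
      labels = best$labels, decisionValues = best$dv,
      bestParams = best[c("kernel", "nu", "gamma", "gamma_value", "degree")],
      silhouette = bestSil, gridLog = do.call(rbind, logRows),
      seed = as.integer(seed))
}

silhouetteFromDist <- function(labels, D) {
  s <- cluster::silhouette(ifelse(labels > 0, 1L, 2L), D)
  mean(s[, "sil_width"])
}

#' Silhouette score of a two-group partition
#'
#' Mean over samples of `(b - a) / max(a, b)` with Euclidean distances in
#' the table's feature space (standardize first to reproduce the space the
#' SVM saw). Samples in a singleton class score 0, the standard convention.
#'
#' @param ft a [FeatureTable-class].
#' @param labels vector of two distinct values (e.g. `+1`/`-1`), one per
#'   row; both classes nonempty.
#' @return numeric in `[-1, 1]`.
#' @export
silhouetteScore <- function(ft, labels) {
  X <- featureMatrix(ft)
  stopifnot(length(labels) == nrow(X), nrow(X) >= 3L)
  if (length(unique(labels)) != 2L)
    stop("silhouette undefined: need exactly two nonempty classes")
  silhouetteFromDist(ifelse(labels == max(labels), 1L, -1L), dist(X))
}

#' Per-feature Bhattacharyya distance between inliers and outliers
#'
#' Univariate Gaussian closed form per feature, computed on RAW feature
#' values: `D = 1/4 log(1/4 (s1^2/s2^2 + s2^2/s1^2 + 2)) +
#' 1/4 (m1 - m2)^2 / (s1^2 + s2^2)`, variances floored at `1e-12`.
#' Zero for identical class distributions; grows with separability.
#'
#' @param ft a raw [FeatureTable-class].
#' @param labels `+1`/`-1` vector, one per row.
#' @return data.frame `feature`, `distance`, `undefined` (flag set for all
#'   features when either class has fewer than 2 members).
#' @export
bhattacharyyaDistance <- function(ft, labels) {
  stopifnot(length(labels) == nrow(ft@table))
  X <- featureMatrix(ft)
  a <- X[labels > 0, , drop = FALSE]
  b <- X[labels < 0, , drop = FALSE]
  undef <- nrow(a) < 2L || nrow(b) < 2L
  if (undef) {
    return(data.frame(feature = featureNames(), distance = NA_real_,
                      undefined = TRUE))
  }
  d <- vapply(seq_len(ncol(X)), function(j) {
    v1 <- max(var2(a[, j]), 1e-12)
    v2 <- max(var2(b[, j]), 1e-12)
    0.25 * log(0.25 * (v1 / v2 + v2 / v1 + 2)) +
      0.25 * (mean(a[, j]) - mean(b[, j]))^2 / (v1 + v2)
  }, numeric(1))
  data.frame(feature = featureNames(), distance = d, undefined = FALSE)
}

#' 2-D stochastic-neighbor embedding of the feature table
#'
#' A seeded t-SNE projection (perplexity `min(30, (n - 1) / 3)`) for
#' visual inspection of the inlier/outlier structure. The embedding is for
#' export and plotting only; no pipeline decision consumes it.
#'
#' @param ft a standardized [FeatureTable-class] with `n >= 5` rows.
#' @param seed integer seed.
#' @param perplexity optional override.
#' @return `n x 2` numeric matrix, or `NULL` (with a warning) when `n < 5`.
#' @export
embed2d <- function(ft, seed = 1L, perplexity = NULL) {
  stopifnot(scalingState(ft) == "standardized")
  X <- featureMatrix(ft)
  n <- nrow(X)
  if (n < 5L) {
    warning("too few seedlings (n = ", n, ") for a 2-D embedding; skipped")
    return(NULL)
  }
  if (is.null(perplexity)) perplexity <- min(30, (n - 1) / 3)
  set.seed(seed)
  out <- Rtsne::Rtsne(X, dims = 2, perplexity = perplexity, theta = 0,
                      pca = FALSE, check_duplicates = FALSE, max_iter = 500)
  coords <- out$Y
  colnames(coords) <- c("dim1", "dim2")
  coords
}
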