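test_that("standardization z-scores with the population sd", {
  X <- matrix(0, 3, 15)
  X[, 1] <- c(1, 2, 3)
  X[, 2] <- c(5, 5, 5)          # constant column passes through
  X[, 3:15] <- rnorm(39)
  std <- standardizeFeatures(matrixFeatureTable(X))
  Z <- featureMatrix(std)
  expect_equal(Z[, 1], c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(Z[, 2], c(5, 5, 5))
  expect_true(all(featureTable(std)$flag_constant))
  expect_lt(max(abs(colMeans(Z[, 3:15]))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(sweep(Z[, 3:15], 2,
                                        colMeans(Z[, 3:15]))^2)) - 1)),
            1e-9)
  expect_equal(scalingState(std), "standardized")
  expect_error(standardizeFeatures(matrixFeatureTable(X[1, , drop = FALSE])),
               "insufficient")
})

test_that("grid search flags only planted far-out points", {
  # 95 standard-Gaussian points in the plane plus 5 planted at 6 sigma
  # (embedded in the fixed 15-column table; spare columns constant):
  # every seedling the selected model flags must be a planted one
  set.seed(21)
  X <- matrix(0, 100, 15)
  X[, 1:2] <- rnorm(200)
  X[1:5, 1] <- X[1:5, 1] + 6
  res <- fitOcsvm(standardizeFeatures(matrixFeatureTable(X)), seed = 1)
  flagged <- which(anomalyLabels(res) == -1L)
  expect_gt(length(flagged), 0)
  expect_true(all(flagged %in% 1:5))
  expect_true(all(anomalyLabels(res) %in% c(-1L, 1L)))
  expect_true(all(sign(decisionValues(res)) ==
                  ifelse(anomalyLabels(res) > 0, 1, -1) |
                  decisionValues(res) == 0))
  # grid log covers the full default grid
  expect_equal(nrow(gridLog(res)), 3 * 3 * 4)
})

test_that("a single-combination grid is selected verbatim", {
  set.seed(21)
  X <- matrix(0, 100, 15)
  X[, 1:2] <- rnorm(200)
  X[1:5, 1] <- X[1:5, 1] + 6
  space <- ocsvmGrid(kernels = "rbf", nus = 0.05, gammas = list(0.1))
  res <- fitOcsvm(standardizeFeatures(matrixFeatureTable(X)), space,
                  seed = 1)
  expect_equal(bestParams(res)$kernel, "rbf")
  expect_equal(bestParams(res)$nu, 0.05)
  expect_equal(bestParams(res)$gamma, 0.1)
})

test_that("row duplication leaves the fit unchanged per original row", {
  set.seed(23)
  X <- matrix(rnorm(30 * 15), 30, 15); X[1:2, ] <- X[1:2, ] + 4
  Xd <- rbind(X, X)
  space <- ocsvmGrid(kernels = c("linear", "rbf"))
  res <- fitOcsvm(standardizeFeatures(matrixFeatureTable(Xd)), space,
                  seed = 1)
  expect_equal(anomalyLabels(res)[1:30], anomalyLabels(res)[31:60])
})

test_that("every eligible grid combination obeys the nu-bound", {
  for (s in c(31, 32)) {
    tr <- generateScene(sceneConfig(stage = "mid", seed = s, nPlants = 36,
                                    imageSize = c(120L, 120L)))
    ft <- standardizeFeatures(
      buildFeatureTable(truthSegmentation(tr), sceneImage(tr)))
    res <- fitOcsvm(ft, seed = s)
    gl <- gridLog(res)
    n <- nrow(featureTable(ft))
    ok <- gl$note != "" | gl$n_outliers / n <= gl$nu + 0.05
    expect_true(all(ok))
    # the selected model itself satisfies the bound
    expect_lte(mean(anomalyLabels(res) == -1L), bestParams(res)$nu + 0.05)
  }
})

test_that("Bhattacharyya distances match the Gaussian closed form", {
  set.seed(24)
  # identical distributions -> zero for every feature
  X <- matrix(rnorm(60 * 15), 60, 15)
  X2 <- rbind(X, X)
  lab <- rep(c(1L, -1L), each = 60)
  d0 <- bhattacharyyaDistance(matrixFeatureTable(X2), lab)
  expect_true(all(abs(d0$distance) < 1e-12))
  # unit-variance mean shift of 1 -> 0.125: point masses {-1, 1} have
  # population mean 0 and variance exactly 1
  a <- rep(c(-1, 1), 300)
  b <- a + 1
  Xs <- matrix(0, 1200, 15); Xs[, 1] <- c(a, b)
  labs <- rep(c(1L, -1L), each = 600)
  ds <- bhattacharyyaDistance(matrixFeatureTable(Xs), labs)
  expect_equal(ds$distance[1], 0.125, tolerance = 1e-12)
  # sigma ratio 2, equal means: only the log term remains
  v <- rep(c(-1, 1), 300)          # population variance 1
  Xv <- matrix(0, 1200, 15); Xv[, 1] <- c(v, 2 * v)
  dv <- bhattacharyyaDistance(matrixFeatureTable(Xv), labs)
  expect_equal(dv$distance[1], 0.25 * log(0.25 * (1 / 4 + 4 + 2)),
               tolerance = 1e-12)
  # symmetry and affine invariance
  set.seed(25)
  Y <- matrix(rnorm(80 * 15), 80, 15); Y[1:20, ] <- Y[1:20, ] * 2 + 1
  laby <- rep(c(-1L, 1L), c(20, 60))
  d1 <- bhattacharyyaDistance(matrixFeatureTable(Y), laby)
  d2 <- bhattacharyyaDistance(matrixFeatureTable(Y), -laby)
  expect_equal(d1$distance, d2$distance)
  d3 <- bhattacharyyaDistance(matrixFeatureTable(Y * 3.7 - 2), laby)
  expect_equal(d1$distance, d3$distance, tolerance = 1e-9)
  # undersized class -> undefined flag
  du <- bhattacharyyaDistance(matrixFeatureTable(Y),
                              c(-1L, rep(1L, 79)))
  expect_true(all(du$undefined))
})

test_that("silhouette equals the brute-force reference", {
  set.seed(26)
  for (r in 1:10) {
    n <- sample(6:50, 1)
    X <- matrix(rnorm(n * 15), n, 15)
    lab <- sample(c(-1L, 1L), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1] <- -lab[1]
    expect_equal(silhouetteScore(matrixFeatureTable(X), lab),
                 bruteSilhouette(X, lab), tolerance = 1e-9)
  }
  # two tight, far blobs approach 1
  B <- matrix(rnorm(40 * 15, sd = 0.01), 40, 15)
  B[21:40, 1] <- B[21:40, 1] + 100
  expect_gt(silhouetteScore(matrixFeatureTable(B),
                            rep(c(1L, -1L), each = 20)), 0.99)
  # random labels on one blob stay near zero
  set.seed(27)
  R <- matrix(rnorm(60 * 15), 60, 15)
  expect_lt(abs(silhouetteScore(matrixFeatureTable(R),
                                sample(c(1L, -1L), 60, replace = TRUE))),
            0.2)
  # four corners of a square, diagonal pairs as classes: hand computation
  # gives (1 - sqrt(2)) / sqrt(2) for every point
  sq <- matrix(0, 4, 15)
  sq[, 1] <- c(0, 0, 1, 1); sq[, 2] <- c(0, 1, 0, 1)
  expect_equal(silhouetteScore(matrixFeatureTable(sq),
                               c(1L, -1L, -1L, 1L)),
               (1 - sqrt(2)) / sqrt(2), tolerance = 1e-12)
})

test_that("the 2-D embedding is seeded, finite and local", {
  set.seed(28)
  X <- matrix(rnorm(25 * 15), 25, 15)
  std <- standardizeFeatures(matrixFeatureTable(rbind(X, X + 1e-3)))
  e1 <- embed2d(std, seed = 5)
  e2 <- embed2d(std, seed = 5)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(50L, 2L))
  expect_true(all(is.finite(e1)))
  # near-duplicate pairs land close together relative to the spread
  pd <- sqrt(rowSums((e1[1:25, ] - e1[26:50, ])^2))
  spread <- median(dist(e1))
  expect_lt(median(pd) / spread, 0.3)
  tiny <- standardizeFeatures(matrixFeatureTable(matrix(rnorm(45), 3)))
  expect_warning(expect_null(embed2d(tiny, seed = 1)), "too few")
})
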