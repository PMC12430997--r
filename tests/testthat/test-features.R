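test_that("disc morphology approaches analytic circle values", {
  m <- maskMorphology(discMask(50))
  expect_gte(m$solidity, 0.98)
  expect_lte(m$eccentricity, 0.1)
  expect_gte(m$circularity, 0.95); expect_lte(m$circularity, 1.1)
  expect_equal(m$area, sum(discMask(50)))
  expect_equal(m$perimeter, 2 * pi * 50, tolerance = 0.03)
})

test_that("square circularity equals pi/4 with the crack estimator", {
  s <- 40L
  m <- maskMorphology(squareMask(s), perimeterMethod = "crack")
  expect_equal(m$perimeter, 4 * s)
  expect_equal(m$circularity, pi / 4, tolerance = 1e-12)
})

test_that("convex shapes have solidity 1 within discretization", {
  for (msk in list(discMask(20), squareMask(25), ellipseMask(25, 12, 0.4)))
    expect_gte(maskMorphology(msk)$solidity, 0.98)
})

test_that("rasterized ellipses recover analytic eccentricity", {
  for (ab in list(c(40, 20), c(35, 14), c(45, 30))) {
    want <- sqrt(1 - (ab[2] / ab[1])^2)
    for (th in c(0, 0.5, 1.1)) {
      got <- maskMorphology(ellipseMask(ab[1], ab[2], th))$eccentricity
      expect_equal(got, want, tolerance = 0.05)
    }
  }
})

test_that("degenerate masks are flagged, empty masks rejected", {
  expect_error(maskMorphology(matrix(FALSE, 4, 4)), "empty")
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  m <- maskMorphology(one)
  expect_equal(m$area, 1L)
  expect_equal(m$eccentricity, 0)
  expect_equal(m$solidity, 1)
  expect_true(m$flag_circularity)
})

test_that("morphology is invariant under 90-degree rotation and scales correctly", {
  set.seed(3)
  blob <- ellipseMask(18, 9, 0.7) | discMask(12, pad = 9)
  m1 <- maskMorphology(blob)
  m2 <- maskMorphology(t(blob)[ncol(blob):1, ])  # rotate 90 degrees
  expect_identical(m1$area, m2$area)
  expect_equal(m1$solidity, m2$solidity)
  expect_equal(m1$perimeter, m2$perimeter, tolerance = 1e-6)
  expect_equal(m1$eccentricity, m2$eccentricity, tolerance = 1e-6)
  # scaling a disc by 4 multiplies area by ~16 and perimeter by ~4
  a <- maskMorphology(discMask(12)); b <- maskMorphology(discMask(48))
  expect_equal(b$area / a$area, 16, tolerance = 0.05 * 16)
  expect_equal(b$perimeter / a$perimeter, 4, tolerance = 0.05 * 4)
})

test_that("spectral means follow the mask and the ExG formula", {
  img <- flatImage(0.1, 0.9, 0.1, 10, 10)
  msk <- matrix(FALSE, 10, 10); msk[3:7, 3:7] <- TRUE
  s <- maskSpectral(img, msk)
  expect_equal(unlist(s),
               c(mean_red = 0.1, mean_green = 0.9, mean_blue = 0.1,
                 mean_exg = 1.6))
  expect_equal(maskSpectral(flatImage(0.4, 0.4, 0.4, 10, 10), msk)$mean_exg, 0)
  # linearity: half the pixels at exg a, half at exg b
  px <- array(0, c(2, 2, 3)); px[, , 2] <- c(0.5, 0.5, 0.9, 0.9)
  expect_equal(maskSpectral(unitImage(px), matrix(TRUE, 2, 2))$mean_exg,
               (1.0 + 1.8) / 2)
})

test_that("co-occurrence statistics match hand-built matrices", {
  chk <- new("IndexMap", values = matrix(c(0, 1, 1, 0), 2),
             indexName = "gray", sourceId = "t")
  tx <- maskTexture(chk, matrix(TRUE, 2, 2),
                    glcmConfig(levels = 2, offsets = list(c(0L, 1L))))
  # symmetric normalized GLCM is [[0, .5], [.5, 0]]
  expect_equal(tx$glcm_contrast, 1)
  expect_equal(tx$glcm_energy, sqrt(0.5))
  expect_equal(tx$glcm_second_moment, 0.5)
  expect_equal(tx$glcm_dissimilarity, 1)
  expect_equal(tx$glcm_homogeneity, 0.5)

  cst <- new("IndexMap", values = matrix(5, 4, 4), indexName = "gray",
             sourceId = "t")
  tc <- maskTexture(cst, matrix(TRUE, 4, 4), glcmConfig())
  expect_equal(unlist(tc[c("glcm_contrast", "glcm_dissimilarity",
                           "glcm_homogeneity", "glcm_energy",
                           "glcm_correlation", "glcm_second_moment")]),
               c(glcm_contrast = 0, glcm_dissimilarity = 0,
                 glcm_homogeneity = 1, glcm_energy = 1,
                 glcm_correlation = 0, glcm_second_moment = 1))
  expect_true(tc$flag_correlation)

  set.seed(9)
  rnd <- new("IndexMap", values = matrix(runif(400), 20),
             indexName = "gray", sourceId = "t")
  tr <- maskTexture(rnd, matrix(TRUE, 20, 20), glcmConfig())
  expect_lt(abs(tr$glcm_energy^2 - tr$glcm_second_moment), 1e-9)
  expect_true(tr$glcm_correlation >= -1 && tr$glcm_correlation <= 1)
  # full 4-offset set makes the statistics 90-degree-rotation invariant
  rot <- new("IndexMap",
             values = t(rnd@values)[ncol(rnd@values):1, ],
             indexName = "gray", sourceId = "t")
  tro <- maskTexture(rot, matrix(TRUE, 20, 20), glcmConfig())
  for (f in c("glcm_contrast", "glcm_homogeneity", "glcm_energy"))
    expect_equal(tr[[f]], tro[[f]], tolerance = 1e-9)
})

test_that("feature tables are complete, ordered and deterministic", {
  tr <- generateScene(sceneConfig(stage = "mid", seed = 12, nPlants = 9,
                                  imageSize = c(80L, 80L),
                                  anomalyFraction = 0))
  seg <- truthSegmentation(tr)
  ft <- buildFeatureTable(seg, sceneImage(tr))
  tab <- featureTable(ft)
  expect_equal(nrow(tab), sceneCounts(tr))
  expect_equal(tab$instance_id, seq_len(sceneCounts(tr)))
  expect_identical(colnames(featureMatrix(ft)), featureNames())
  expect_false(anyNA(featureMatrix(ft)))
  expect_true(all(tab$solidity > 0 & tab$solidity <= 1))
  expect_true(all(tab$eccentricity >= 0 & tab$eccentricity < 1))
  expect_true(all(tab$glcm_homogeneity > 0 & tab$glcm_homogeneity <= 1))
  expect_true(all(tab$glcm_correlation >= -1 & tab$glcm_correlation <= 1))
  expect_lt(max(abs(tab$glcm_energy^2 - tab$glcm_second_moment)), 1e-9)
  # identical masks produce identical rows
  ft2 <- buildFeatureTable(seg, sceneImage(tr))
  expect_identical(featureTable(ft2), tab)
  # zero instances give a valid empty table
  empty <- new("InstanceSegmentation",
               labelMap = matrix(0L, 10, 10),
               instanceInfo = data.frame(instance_id = integer(0),
                                         prompt_row = numeric(0),
                                         prompt_col = numeric(0),
                                         score = numeric(0),
                                         area_px = integer(0)),
               sourceId = "e")
  img <- flatImage(0.2, 0.2, 0.2, 10, 10)
  expect_equal(nrow(featureTable(buildFeatureTable(empty, img))), 0L)
})
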