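test_that("multi-Otsu separates two-value and three-cluster maps", {
  v <- c(rep(0, 900), rep(10, 100))
  m <- new("IndexMap", values = matrix(v, 25), indexName = "ExGR",
           sourceId = "t")
  bm <- multiOtsu(m, nClasses = 2)
  thr <- thresholds(bm)
  expect_length(thr, 1)
  expect_gt(thr, 0); expect_lt(thr, 10)
  expect_equal(sum(vegetationMask(bm)), 100)

  cst <- new("IndexMap", values = matrix(1, 5, 5), indexName = "ExGR",
             sourceId = "t")
  expect_error(multiOtsu(cst, 2), "degenerate")

  v3 <- c(rep(0, 500), rep(5, 300), rep(10, 200))
  m3 <- new("IndexMap", values = matrix(v3, 25), indexName = "ExGR",
            sourceId = "t")
  bm3 <- multiOtsu(m3, nClasses = 3)
  expect_equal(sum(vegetationMask(bm3)), 200)  # only the top cluster
  expect_length(thresholds(bm3), 2)
})

test_that("histogram split search matches exhaustive variance search", {
  set.seed(7)
  for (r in 1:20) {
    counts <- rpois(256, lambda = runif(1, 1, 20))
    spikes <- sample(256, 3)
    counts[spikes] <- counts[spikes] + rpois(3, 200)
    expect_identical(seedlingHealth:::otsuSplit(counts, 1L),
                     bruteOtsu1(counts))
  }
  set.seed(8)
  for (r in 1:5) {  # smaller histograms keep the exhaustive pair search fast
    counts <- rpois(48, lambda = 5)
    spikes <- sample(48, 3)
    counts[spikes] <- counts[spikes] + 150L
    expect_identical(seedlingHealth:::otsuSplit(counts, 2L),
                     bruteOtsu2(counts))
  }
})

test_that("connected components honour the requested connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE  # touch diagonally
  expect_equal(max(labelComponents(m, 4L)), 2L)
  expect_equal(max(labelComponents(m, 8L)), 1L)
})

test_that("prompts carry tight boxes and centered points", {
  m <- matrix(FALSE, 30, 40)
  m[11:15, 21:25] <- TRUE  # 0-based rows 10-14, cols 20-24
  bm <- new("BinaryMap", mask = m, thresholds = 0, nClasses = 2L)
  ps <- componentsToPrompts(bm, minArea = 1L)
  expect_equal(nInstances(ps), 1L)
  expect_equal(as.vector(promptBoxes(ps)[1, ]), c(10, 20, 15, 25))
  expect_equal(as.vector(promptPoints(ps)[1, ]), c(12, 22))

  # min-area filter: 9 px and 2 px blocks, threshold at 4 px
  m2 <- matrix(FALSE, 20, 20)
  m2[2:4, 2:4] <- TRUE
  m2[10, 10:11] <- TRUE
  bm2 <- new("BinaryMap", mask = m2, thresholds = 0, nClasses = 2L)
  expect_equal(nInstances(componentsToPrompts(bm2, minArea = 4L)), 1L)

  # empty mask is a valid zero-prompt outcome
  bm0 <- new("BinaryMap", mask = matrix(FALSE, 5, 5), thresholds = 0,
             nClasses = 2L)
  expect_equal(nInstances(componentsToPrompts(bm0)), 0L)
})

test_that("prompt extraction is translation invariant and area-faithful", {
  set.seed(11)
  base <- matrix(runif(40 * 40) > 0.82, 40, 40)
  bm <- new("BinaryMap", mask = base, thresholds = 0, nClasses = 2L)
  ps <- componentsToPrompts(bm, minArea = 3L)
  shifted <- matrix(FALSE, 50, 50)
  shifted[6:45, 9:48] <- base
  ps2 <- componentsToPrompts(new("BinaryMap", mask = shifted,
                                 thresholds = 0, nClasses = 2L),
                             minArea = 3L)
  expect_equal(nInstances(ps2), nInstances(ps))
  expect_equal(promptBoxes(ps2)[, c(1, 3)] - 5, promptBoxes(ps)[, c(1, 3)])
  expect_equal(promptBoxes(ps2)[, c(2, 4)] - 8, promptBoxes(ps)[, c(2, 4)])
  # every box holds at least minArea true pixels of the mask
  for (i in seq_len(nInstances(ps))) {
    b <- promptBoxes(ps)[i, ]
    expect_gte(sum(base[(b[1] + 1):b[3], (b[2] + 1):b[4]]), 3)
  }
  # points always lie inside their boxes (validity also enforces this)
  p <- promptPoints(ps); b <- promptBoxes(ps)
  expect_true(all(p[, 1] >= b[, 1] & p[, 1] < b[, 3] &
                  p[, 2] >= b[, 2] & p[, 2] < b[, 4]))
})

test_that("centroid prompt mode returns component centroids", {
  m <- matrix(FALSE, 12, 12)
  m[3:5, 3:5] <- TRUE; m[3, 6:8] <- TRUE  # L-shape
  bm <- new("BinaryMap", mask = m, thresholds = 0, nClasses = 2L)
  ps <- componentsToPrompts(bm, minArea = 1L, center = "centroid")
  idx <- which(m, arr.ind = TRUE) - 1
  expect_equal(as.vector(promptPoints(ps)[1, ]),
               c(mean(idx[, 1]), mean(idx[, 2])))
})

test_that("prompt sets round-trip through the JSON prompt file", {
  m <- matrix(FALSE, 20, 20); m[3:6, 3:7] <- TRUE; m[12:16, 10:13] <- TRUE
  ps <- componentsToPrompts(new("BinaryMap", mask = m, thresholds = 0,
                                nClasses = 2L), minArea = 1L,
                            sourceId = "rt")
  f <- tempfile(fileext = ".json")
  writePrompts(ps, f)
  back <- readPrompts(f)
  expect_equal(promptBoxes(back), promptBoxes(ps), ignore_attr = TRUE)
  expect_equal(promptPoints(back), promptPoints(ps), ignore_attr = TRUE)
  expect_identical(back@componentIds, ps@componentIds)
})
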