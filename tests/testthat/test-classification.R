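# helper: detections with hand-set marker means on a minimal label image
fakeFeatures <- function(clec4f, tim4) {
  n <- length(clec4f)
  lab <- matrix(0L, 2, n)
  lab[1, ] <- seq_len(n)
  det <- detectionsFromLabels(lab)
  tb <- featureTable(det)
  tb[[featureColumn("CLEC4F")]] <- clec4f
  tb[[featureColumn("TIM4")]] <- tim4
  CellDetections(lab, tb)
}

test_that("feature extraction reproduces exact means", {
  lab <- matrix(0L, 10, 10)
  lab[2:3, 2:3] <- 1L
  lab[6:9, 6:7] <- 2L
  uniform <- matrix(7, 10, 10)
  half <- matrix(0, 10, 10)
  half[, 6] <- 100                      # half of cell 2's 4x2 mask
  img <- MultiplexImage(list("F4/80" = uniform, "CLEC4F" = half))
  det <- extractFeatures(detectionsFromLabels(lab), img)
  tb <- featureTable(det)
  expect_equal(tb$mean_F480, c(7, 7))
  expect_equal(tb$mean_CLEC4F[2], 50)   # direct pixel sum: (4*100 + 4*0) / 8
  expect_equal(tb$mean_CLEC4F[1], 0)
})

test_that("feature extraction of an empty detection set is an empty table", {
  img <- MultiplexImage(list("F4/80" = matrix(1, 6, 6)))
  det <- extractFeatures(CellDetections(matrix(0L, 6, 6)), img)
  expect_equal(nDetections(det), 0)
  expect_true(featureColumn("F4/80") %in% names(featureTable(det)))
})

test_that("feature extraction rejects mismatched geometry", {
  img <- MultiplexImage(list("F4/80" = matrix(1, 6, 6)))
  expect_error(extractFeatures(CellDetections(matrix(0L, 5, 5)), img),
               "geometry")
})

test_that("the marker gate assigns ResKC / moKC / C4negMac correctly", {
  det <- fakeFeatures(clec4f = c(200, 200, 10, 10),
                      tim4 = c(200, 10, 200, 10))
  out <- classifyCells(det, classParams(threshold_mode = "fixed",
                                        clec4f_threshold = 100,
                                        tim4_threshold = 100))
  expect_identical(featureTable(out)$class,
                   c("ResKC", "moKC", "C4negMac", "C4negMac"))
})

test_that("a mean exactly at the threshold counts as positive", {
  det <- fakeFeatures(clec4f = c(100, 99.999), tim4 = c(100, 100))
  out <- classifyCells(det, classParams(threshold_mode = "fixed",
                                        clec4f_threshold = 100,
                                        tim4_threshold = 100))
  expect_identical(featureTable(out)$class, c("ResKC", "C4negMac"))
})

test_that("noise-free synthetic classification agrees 100% with truth", {
  sim <- generateTissueImage(tissueSpec(imageShape = c(384, 384),
    nCells = c(ResKC = 15, moKC = 10, C4negMac = 10, distractor = 4),
    nHiPatches = 1, hiPatchRadius = 60, nVessels = 0, noiseSd = 0,
    seed = 23))
  det <- detectMacrophages(sim$image, detectionParams(
    threshold_mode = "fixed", threshold_value = 100, min_area = 20))
  expect_equal(nDetections(det), 35)    # distractors invisible to F4/80
  det <- classifyCells(extractFeatures(det, sim$image),
                       classParams(threshold_mode = "fixed",
                                   clec4f_threshold = 100,
                                   tim4_threshold = 100))
  hit <- matchToTruth(det, sim$truth)
  expect_identical(featureTable(det)$class, sim$truth$class[hit])
})

test_that("class labels partition the detections", {
  det <- fakeFeatures(clec4f = runif(20, 0, 200), tim4 = runif(20, 0, 200))
  out <- classifyCells(det, classParams(threshold_mode = "fixed",
                                        clec4f_threshold = 100,
                                        tim4_threshold = 100))
  tab <- table(featureTable(out)$class)
  expect_equal(sum(tab), 20)
})

test_that("raising thresholds is monotone in the gated counts", {
  set.seed(31)
  c4 <- runif(60, 0, 200); t4 <- runif(60, 0, 200)
  nResKC <- function(thT) sum(featureTable(classifyCells(fakeFeatures(c4, t4),
    classParams(threshold_mode = "fixed", clec4f_threshold = 80,
                tim4_threshold = thT)))$class == "ResKC")
  expect_true(all(diff(vapply(c(20, 60, 120, 180), nResKC, numeric(1))) <= 0))
  nC4pos <- function(thC) sum(featureTable(classifyCells(fakeFeatures(c4, t4),
    classParams(threshold_mode = "fixed", clec4f_threshold = thC,
                tim4_threshold = 80)))$class != "C4negMac")
  expect_true(all(diff(vapply(c(20, 60, 120, 180), nC4pos, numeric(1))) <= 0))
})

test_that("row order does not change per-cell labels", {
  set.seed(37)
  det <- fakeFeatures(clec4f = runif(15, 0, 200), tim4 = runif(15, 0, 200))
  p <- classParams(threshold_mode = "fixed", clec4f_threshold = 100,
                   tim4_threshold = 100)
  a <- featureTable(classifyCells(det, p))
  perm <- sample(nrow(a))
  det2 <- CellDetections(labelImage(det), featureTable(det)[perm, ])
  b <- featureTable(classifyCells(det2, p))
  expect_identical(b$class[match(a$cell_id, b$cell_id)], a$class)
})

test_that("otsu-on-cell-means refuses fewer than 3 cells", {
  det <- fakeFeatures(clec4f = c(10, 200), tim4 = c(10, 200))
  expect_error(classifyCells(det, classParams()), "fixed thresholds")
})

test_that("otsu-on-cell-means separates well-split marker populations", {
  set.seed(41)
  c4 <- c(rnorm(20, 20, 3), rnorm(20, 180, 3))
  t4 <- c(rnorm(30, 20, 3), rnorm(10, 180, 3))
  out <- featureTable(classifyCells(fakeFeatures(c4, t4), classParams()))
  expect_equal(sum(out$class == "C4negMac"), 20)
  expect_equal(sum(out$class == "ResKC"), sum(c4 >= 100 & t4 >= 100))
})
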