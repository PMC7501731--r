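test_that("median filter: identity at radius 0, constancy, salt removal", {
  m <- matrix(runif(30 * 20, 0, 255), 30, 20)
  expect_identical(medianFilterChannel(m, 0), m)
  k <- matrix(7, 15, 15)
  expect_true(all(medianFilterChannel(k, 3) == 7))
  salt <- matrix(10, 21, 21)
  salt[11, 11] <- 200
  expect_true(all(medianFilterChannel(salt, 2) == 10))
})

test_that("median filter equals the brute-force window median everywhere", {
  set.seed(42)
  for (r in c(1, 2, 3)) {
    m <- matrix(sample(0:255, 18 * 14, replace = TRUE), 18, 14)
    expect_equal(medianFilterChannel(m, r), bruteMedian(m, r),
                 ignore_attr = TRUE)
  }
})

test_that("thresholding uses the >= convention and handles degenerate input", {
  m <- matrix(c(99, 100, 101), 1, 3)
  p <- detectionParams(threshold_mode = "fixed", threshold_value = 100)
  expect_identical(as.vector(thresholdChannel(m, p)), c(FALSE, TRUE, TRUE))
  z <- matrix(0, 5, 5)
  expect_true(all(!thresholdChannel(z, detectionParams(
    threshold_mode = "fixed", threshold_value = 1))))
  expect_warning(
    out <- thresholdChannel(matrix(5, 5, 5),
                            detectionParams(threshold_mode = "global-otsu")),
    "constant")
  expect_true(all(!out))
})

test_that("global Otsu separates a clean bimodal image exactly", {
  set.seed(1)
  truth <- matrix(runif(40 * 40) < 0.3, 40, 40)
  m <- matrix(10, 40, 40)
  m[truth] <- 200
  p <- detectionParams(threshold_mode = "global-otsu")
  got <- thresholdChannel(m, p)
  expect_identical(got, truth)
  # and the EBImage-backed cut agrees with the exhaustive variance search
  tOracle <- exhaustiveOtsu(m)
  expect_true(all((m >= tOracle) == got))
})

test_that("disks are detected with exact digital-disk areas", {
  centers <- rbind(c(20, 20), c(20, 60), c(60, 20), c(60, 60), c(40, 90))
  img <- diskImage(110, 110, centers, radius = 10, fg = 200, bg = 10)
  # median filter off: the oracle is the exact digital-disk lattice count
  det <- detectMacrophages(img, detectionParams(threshold_mode = "fixed",
    threshold_value = 100, min_area = 50, tile_size = 128,
    median_radius = 0))
  expect_equal(nDetections(det), 5)
  expect_true(all(featureTable(det)$area_px == latticeDiskCount(10)))
})

test_that("a disk straddling a tile boundary is detected once, identically to untiled", {
  img <- diskImage(256, 256, cbind(128.5, 100), radius = 12)
  p <- function(ts) detectionParams(threshold_mode = "fixed",
    threshold_value = 100, min_area = 20, tile_size = ts)
  tiled <- detectMacrophages(img, p(128))
  whole <- detectMacrophages(img, p(256))
  expect_equal(nDetections(tiled), 1)
  expect_identical(labelImage(tiled), labelImage(whole))
  expect_equal(featureTable(tiled), featureTable(whole))
})

test_that("hole filling turns an annulus into a full disk; idempotent", {
  nr <- 41
  d2 <- outer((1:nr - 21)^2, (1:nr - 21)^2, "+")
  ann <- matrix(10, nr, nr)
  ann[d2 <= 15^2 & d2 >= 10^2] <- 200
  img <- MultiplexImage(list("F4/80" = ann))
  det <- detectMacrophages(img, detectionParams(threshold_mode = "fixed",
    threshold_value = 100, min_area = 10, tile_size = 64, median_radius = 0))
  expect_equal(featureTable(det)$area_px, sum(d2 <= 15^2))
  mask <- matrix(d2 <= 15^2 & d2 >= 10^2, nr, nr)
  once <- fillHoles(mask, 8)
  expect_identical(fillHoles(once, 8), once)
})

test_that("min_area filter boundary: area-1 removed, exact area retained", {
  lab <- matrix(10, 30, 30)
  lab[5:6, 5:7] <- 200      # 6 px
  lab[15:16, 15:18] <- 200  # 8 px
  img <- MultiplexImage(list("F4/80" = lab))
  p <- function(a) detectionParams(threshold_mode = "fixed",
    threshold_value = 100, min_area = a, tile_size = 32, median_radius = 0)
  expect_equal(nDetections(detectMacrophages(img, p(7))), 1)
  expect_equal(nDetections(detectMacrophages(img, p(8))), 1)
  expect_equal(nDetections(detectMacrophages(img, p(6))), 2)
  expect_equal(nDetections(detectMacrophages(img, p(9))), 0)
})

test_that("an all-background channel yields an empty detection set", {
  img <- MultiplexImage(list("F4/80" = matrix(5, 64, 64)))
  det <- detectMacrophages(img, detectionParams(threshold_mode = "fixed",
    threshold_value = 100))
  expect_equal(nDetections(det), 0)
})

test_that("detection requires the F4/80 channel", {
  img <- MultiplexImage(list("Desmin" = matrix(5, 16, 16)))
  expect_error(detectMacrophages(img), "F4/80")
})

test_that("tiling invariance holds across tile sizes under global thresholds", {
  sim <- generateTissueImage(tissueSpec(imageShape = c(320, 320),
    nCells = c(ResKC = 20, moKC = 10, C4negMac = 10, distractor = 3),
    nHiPatches = 1, hiPatchRadius = 60, nVessels = 1, seed = 13))
  for (mode in c("fixed", "global-otsu")) {
    p <- function(ts) detectionParams(threshold_mode = mode,
      threshold_value = 100, min_area = 20, tile_size = ts)
    ref <- detectMacrophages(sim$image, p(320))
    for (ts in c(64, 128, 256)) {
      det <- detectMacrophages(sim$image, p(ts))
      expect_identical(labelImage(det), labelImage(ref))
    }
  }
})

test_that("detections are disjoint and their union is the filtered mask", {
  sim <- generateTissueImage(tissueSpec(imageShape = c(256, 256),
    nCells = c(ResKC = 12, moKC = 6, C4negMac = 6, distractor = 2),
    nHiPatches = 0, nVessels = 0, seed = 17))
  det <- detectMacrophages(sim$image, detectionParams(threshold_mode = "fixed",
    threshold_value = 100, min_area = 20))
  lab <- labelImage(det)
  tb <- featureTable(det)
  # label image partitions foreground: per-cell areas sum to foreground area
  expect_equal(sum(tb$area_px), sum(lab > 0))
  expect_equal(sort(unique(as.vector(lab[lab > 0]))), tb$cell_id)
})

test_that("raising min_area or the threshold is monotone", {
  sim <- generateTissueImage(tissueSpec(imageShape = c(256, 256),
    nCells = c(ResKC = 10, moKC = 5, C4negMac = 5, distractor = 0),
    nHiPatches = 0, nVessels = 0, seed = 19))
  counts <- vapply(c(10, 50, 120, 400), function(a)
    nDetections(detectMacrophages(sim$image, detectionParams(
      threshold_mode = "fixed", threshold_value = 100, min_area = a))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
  areas <- vapply(c(50, 100, 150, 250), function(t)
    sum(featureTable(detectMacrophages(sim$image, detectionParams(
      threshold_mode = "fixed", threshold_value = t, min_area = 1)))$area_px),
    numeric(1))
  expect_true(all(diff(areas) <= 0))
})
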