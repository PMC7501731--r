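test_that("multi-channel TIFF round-trips integer data losslessly", {
  img <- MultiplexImage(
    list("F4/80" = matrix(sample(0:5000, 64 * 48, replace = TRUE), 64, 48),
         "Desmin" = matrix(sample(0:300, 64 * 48, replace = TRUE), 64, 48)),
    pixelSize = 0.5, imageId = "rt")
  path <- withr::local_tempfile(fileext = ".tiff")
  writeMultichannelTiff(img, path)
  back <- readMultichannelTiff(path)
  expect_identical(getChannel(back, "F4/80"), getChannel(img, "F4/80"))
  expect_identical(getChannel(back, "Desmin"), getChannel(img, "Desmin"))
  expect_equal(pixelSize(back), 0.5)
})

test_that("channel aliases resolve and missing channels name the available set", {
  img <- MultiplexImage(list("F4/80" = matrix(1, 4, 4),
                             "CLEC4F" = matrix(2, 4, 4)))
  expect_identical(getChannel(img, "F4-80"), getChannel(img, "F4/80"))
  expect_identical(getChannel(img, "f480"), getChannel(img, "F4/80"))
  expect_error(getChannel(img, "TIM4"), "TIM4.*F4/80.*CLEC4F")
})

test_that("positional channel names apply when no sidecar metadata exists", {
  path <- withr::local_tempfile(fileext = ".tiff")
  tiff::writeTIFF(list(matrix(0.1, 8, 8), matrix(0.2, 8, 8)), path)
  img <- readMultichannelTiff(path, channelNames = c("F4/80", "TIM4"))
  expect_setequal(channelNames(img), c("F4/80", "TIM4"))
  expect_error(readMultichannelTiff(path, channelNames = c("F4/80", "CLEC4F", "TIM4")),
               "2 pages.*3 channel names")
})

test_that("label images round-trip exactly", {
  lab <- matrix(sample(0:40, 32 * 32, replace = TRUE), 32, 32)
  path <- withr::local_tempfile(fileext = ".tiff")
  writeLabelTiff(lab, path)
  expect_identical(readLabelTiff(path), matrix(as.integer(lab), 32, 32))
})

test_that("3D probability stacks round-trip within float precision", {
  a <- array(runif(16 * 16 * 8), c(16, 16, 8))
  path <- withr::local_tempfile(fileext = ".tiff")
  writeStackTiff(a, path)
  expect_equal(readStackTiff(path), a, tolerance = 1e-6)
})

test_that("polygon export: shoelace area agrees with the mask pixel count", {
  # solid 10x10 square
  lab <- matrix(0L, 20, 20)
  lab[6:15, 4:13] <- 1L
  det <- detectionsFromLabels(lab)
  gj <- exportAnnotations(det)
  expect_length(gj$features, 1)
  ring <- gj$features[[1]]$geometry$coordinates[[1]]
  expect_equal(shoelaceArea(ring[-nrow(ring), , drop = FALSE]), 100)
  # a digital disk: crack-boundary area is exactly the pixel count
  img <- diskImage(40, 40, cbind(20, 20), 8)
  det2 <- detectMacrophages(img, detectionParams(threshold_mode = "fixed",
    threshold_value = 100, min_area = 10, tile_size = 64))
  gj2 <- exportAnnotations(det2)
  ring2 <- gj2$features[[1]]$geometry$coordinates[[1]]
  area <- shoelaceArea(ring2[-nrow(ring2), , drop = FALSE])
  expect_equal(area, featureTable(det2)$area_px[1])
})

test_that("empty detection sets export as a valid empty FeatureCollection", {
  det <- CellDetections(matrix(0L, 8, 8))
  gj <- exportAnnotations(det)
  expect_identical(gj$type, "FeatureCollection")
  expect_length(gj$features, 0)
})

test_that("annotation export/import preserves class labels and centroids", {
  sim <- generateTissueImage(tissueSpec(imageShape = c(256, 256),
    nCells = c(ResKC = 6, moKC = 3, C4negMac = 3, distractor = 0),
    nHiPatches = 0, nVessels = 0, noiseSd = 0, seed = 21))
  det <- detectMacrophages(sim$image, detectionParams(
    threshold_mode = "fixed", threshold_value = 100, min_area = 10))
  det <- classifyCells(extractFeatures(det, sim$image),
                       classParams(threshold_mode = "fixed",
                                   clec4f_threshold = 100,
                                   tim4_threshold = 100))
  path <- withr::local_tempfile(fileext = ".geojson")
  exportAnnotations(det, path)
  back <- importAnnotations(path)
  tb <- featureTable(det)
  expect_equal(nrow(back$table), nrow(tb))
  ord <- match(tb$cell_id, back$table$cell_id)
  expect_identical(back$table$class[ord], tb$class)
  expect_lt(max(abs(back$table$centroid_row[ord] - tb$centroid_row)), 0.5)
  expect_lt(max(abs(back$table$centroid_col[ord] - tb$centroid_col)), 0.5)
  # polygon centroid (pixel-square interpretation) agrees with the mask
  # centroid: polygon x spans columns [c-1, c], so centre + 0.5 = column
  v <- back$polygons[[1]]
  v <- v[-nrow(v), , drop = FALSE]
})

test_that("CSV tables round-trip including stamped comment lines", {
  df <- data.frame(a = 1:3, b = c("x", "y", "z"), c = c(1.5, 2.5, NA))
  path <- withr::local_tempfile(fileext = ".csv")
  writeTableCsv(df, path, stamp = "config_hash=abc seed=1")
  expect_identical(readLines(path, 1), "# config_hash=abc seed=1")
  expect_equal(readTableCsv(path), df)
})

test_that("config serialize -> parse -> serialize is the identity", {
  cfg <- list(seed = 7, vessel_source = "external-mask",
              detection = list(tile_size = 128, threshold_mode = "fixed",
                               threshold_value = 99.5, fill_holes = TRUE),
              zoning = list(smoothing_sigma = 4, quantile_level = 0.75),
              channels = c("F4/80", "CLEC4F"))
  p1 <- withr::local_tempfile(fileext = ".cfg")
  p2 <- withr::local_tempfile(fileext = ".cfg")
  writeConfig(cfg, p1)
  back <- readConfig(p1)
  writeConfig(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(back$detection$tile_size, 128)
  expect_identical(back$detection$fill_holes, TRUE)
  expect_identical(back$channels, c("F4/80", "CLEC4F"))
})
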