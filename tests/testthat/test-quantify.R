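# detections with hand-set class labels and centroid positions
fakeClassified <- function(rows, cols, classes, shape = c(64, 64)) {
  n <- length(classes)
  lab <- matrix(0L, shape[1], shape[2])
  lab[cbind(rows, cols)] <- seq_len(n)
  det <- detectionsFromLabels(lab)
  tb <- featureTable(det)
  tb$class <- classes[tb$cell_id]
  CellDetections(lab, tb)
}

test_that("zone assignment reads the label at the centroid", {
  det <- fakeClassified(c(10, 20, 30), c(10, 20, 30),
                        c("ResKC", "moKC", "C4negMac"))
  zmAllLo <- ZoneMap(matrix(1L, 64, 64))
  out <- assignZones(det, zmAllLo)
  expect_identical(featureTable(out)$zone, rep("Lo", 3))
  lab <- matrix(1L, 64, 64)
  lab[1:15, ] <- 2L
  lab[, 25:40] <- 0L
  out2 <- assignZones(det, ZoneMap(lab))
  expect_identical(featureTable(out2)$zone, c("Hi", "Lo", "excluded"))
})

test_that("cells inside vessels are excluded from every percentage", {
  det <- fakeClassified(c(10, 20, 30, 40), c(10, 20, 30, 40),
                        rep("ResKC", 4))
  lab <- matrix(1L, 64, 64)
  lab[38:42, 38:42] <- 0L                 # vessel over the 4th cell
  comp <- quantifyComposition(assignZones(det, ZoneMap(lab)))
  expect_true(all(comp$n_excluded_cells == 1))
  allRow <- comp[comp$zone == "all" & comp$class == "ResKC", ]
  expect_equal(allRow$count, 3)
  expect_equal(allRow$pct_of_total_macs, 100)
})

test_that("assigned zones equal truth zones away from boundaries", {
  sim <- generateTissueImage(tissueSpec(imageShape = c(384, 384),
    nCells = c(ResKC = 20, moKC = 10, C4negMac = 10, distractor = 0),
    nHiPatches = 1, hiPatchRadius = 80, nVessels = 1, noiseSd = 0,
    seed = 43))
  det <- detectMacrophages(sim$image, detectionParams(
    threshold_mode = "fixed", threshold_value = 100, min_area = 20))
  det <- classifyCells(extractFeatures(det, sim$image),
                       classParams(threshold_mode = "fixed",
                                   clec4f_threshold = 100,
                                   tim4_threshold = 100))
  det <- assignZones(det, sim$zones)     # truth map: exact agreement
  hit <- matchToTruth(det, sim$truth)
  expect_identical(featureTable(det)$zone, sim$truth$zone[hit])
})

test_that("single-class composition reports 100% and zeros elsewhere", {
  det <- fakeClassified(seq(5, 50, by = 5), seq(5, 50, by = 5),
                        rep("ResKC", 10))
  comp <- quantifyComposition(assignZones(det, ZoneMap(matrix(1L, 64, 64))))
  expect_equal(comp$pct_of_total_macs[comp$zone == "all" &
                                        comp$class == "ResKC"], 100)
  expect_equal(comp$pct_of_total_macs[comp$zone == "all" &
                                        comp$class == "moKC"], 0)
  # absent classes report missing, not zero, zone percentages
  expect_true(is.na(comp$pct_of_class_in_zone[comp$zone == "Hi" &
                                                comp$class == "moKC"]))
})

test_that("composition sums are exact: totals 100, Hi + Lo = 100 per class", {
  set.seed(47)
  n <- 60
  pos <- expand.grid(r = seq(5, 60, by = 5), c = seq(5, 60, by = 5))
  pos <- pos[sample(nrow(pos), n), ]
  det <- fakeClassified(pos$r, pos$c,
                        sample(c("ResKC", "moKC", "C4negMac"), n, TRUE),
                        shape = c(64, 64))
  lab <- matrix(1L, 64, 64)
  lab[1:30, ] <- 2L
  comp <- quantifyComposition(assignZones(det, ZoneMap(lab)))
  expect_equal(sum(comp$pct_of_total_macs[comp$zone == "all"]), 100)
  for (cl in unique(comp$class)) {
    nC <- comp$count[comp$zone == "all" & comp$class == cl]
    if (nC > 0)
      expect_equal(sum(comp$pct_of_class_in_zone[comp$zone %in% c("Hi", "Lo") &
                                                   comp$class == cl]), 100)
  }
  # count conservation over classes and zones
  expect_equal(sum(comp$count[comp$zone %in% c("Hi", "Lo")]) +
                 comp$n_excluded_cells[1], nDetections(det))
})

test_that("zero non-excluded cells yield missing percentages and a warning", {
  det <- fakeClassified(c(10, 20), c(10, 20), rep("ResKC", 2))
  expect_warning(comp <- quantifyComposition(
    assignZones(det, ZoneMap(matrix(0L, 64, 64)))), "missing")
  expect_true(all(comp$count == 0))
  expect_true(all(is.na(comp$pct_of_total_macs)))
})

test_that("planted zone composition is recovered within 3 points at n = 500", {
  sim <- generateTissueImage(tissueSpec(seed = 51))   # defaults: 500 macs
  det <- detectMacrophages(sim$image, detectionParams(min_area = 20))
  det <- classifyCells(extractFeatures(det, sim$image))
  zm <- applyVesselExclusion(segmentDesminZones(sim$image), sim$vesselMask)
  det <- assignZones(det, zm)
  comp <- quantifyComposition(det)
  truth <- sim$truth[sim$truth$class != "distractor" &
                       sim$truth$zone != "excluded", ]
  for (cl in c("ResKC", "moKC", "C4negMac")) {
    want <- 100 * sum(truth$class == cl) / nrow(truth)
    got <- comp$pct_of_total_macs[comp$zone == "all" & comp$class == cl]
    expect_lt(abs(got - want), 3)
  }
})

test_that("C4negMac enrichment direction follows the configured rho", {
  sim <- generateTissueImage(tissueSpec(seed = 53))   # enrichmentRho = 4
  det <- detectMacrophages(sim$image, detectionParams(min_area = 20))
  det <- classifyCells(extractFeatures(det, sim$image))
  zm <- applyVesselExclusion(segmentDesminZones(sim$image), sim$vesselMask)
  comp <- quantifyComposition(assignZones(det, zm))
  kept <- featureTable(assignZones(det, zm))
  kept <- kept[kept$zone != "excluded", ]
  pctHi <- 100 * sum(kept$class == "C4negMac" & kept$zone == "Hi") /
    sum(kept$zone == "Hi")
  pctLo <- 100 * sum(kept$class == "C4negMac" & kept$zone == "Lo") /
    sum(kept$zone == "Lo")
  expect_gt(pctHi, pctLo)
})
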