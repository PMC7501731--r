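# Subset composition statistics: percentage of each class among all
# non-excluded macrophages, and the per-zone split of each class between
# Desmin-high and Desmin-low tissue, with vessel-region cells excluded.

.macClasses <- c("ResKC", "moKC", "C4negMac")

#' Assign each detected cell to a tissue zone
#'
#' A cell's zone is the zone-map label at its centroid pixel (nearest pixel
#' to the sub-pixel centroid). Cells whose centroid falls in an excluded
#' (vessel) pixel are marked \code{"excluded"} and drop out of all
#' percentages downstream.
#'
#' @param detections A \linkS4class{CellDetections}.
#' @param zonemap A \linkS4class{ZoneMap} of the same geometry.
#' @return The \linkS4class{CellDetections} with a \code{zone} column
#'   (\code{"Hi"}, \code{"Lo"} or \code{"excluded"}).
#' @export
assignZones <- function(detections, zonemap) {
  stopifnot(is(detections, "CellDetections"), is(zonemap, "ZoneMap"))
  lab <- zoneLabels(zonemap)
  if (!identical(dim(labelImage(detections)), dim(lab)))
    stop("zone map shape does not match the detection geometry", call. = FALSE)
  tb <- featureTable(detections)
  if (nrow(tb)) {
    r <- round(tb$centroid_row)
    c <- round(tb$centroid_col)
    if (any(r < 1 | r > nrow(lab) | c < 1 | c > ncol(lab)))
      stop("cell centroid outside the image", call. = FALSE)
    tb$zone <- c("excluded", "Lo", "Hi")[lab[cbind(r, c)] + 1L]
  } else {
    tb$zone <- character(0)
  }
  detections@table <- tb
  validObject(detections)
  detections
}

#' Subset composition overall and per Desmin zone
#'
#' Computes, per image: for every class the count and the percentage of all
#' non-excluded macrophages (zone \code{"all"}), and for the Desmin-high
#' and Desmin-low zones the per-zone count and the percentage of that class
#' found in the zone. Percentages with an empty denominator are reported as
#' missing (NA), never as 0. With zero non-excluded cells all percentages
#' are missing and a warning is raised.
#'
#' @param detections A \linkS4class{CellDetections} with \code{class} and
#'   \code{zone} columns.
#' @return A data.frame with columns image_id, zone (\code{"all"},
#'   \code{"Hi"}, \code{"Lo"}), class, count, pct_of_total_macs,
#'   pct_of_class_in_zone, n_excluded_cells.
#' @examples
#' sim <- generateTissueImage(tissueSpec(imageShape = c(384, 384),
#'   nCells = c(ResKC = 20, moKC = 10, C4negMac = 10, distractor = 0),
#'   nHiPatches = 1, hiPatchRadius = 80, nVessels = 0, noiseSd = 0, seed = 3))
#' det <- detectMacrophages(sim$image, detectionParams(
#'   threshold_mode = "fixed", threshold_value = 100, min_area = 10))
#' det <- classifyCells(extractFeatures(det, sim$image),
#'   classParams(threshold_mode = "fixed", clec4f_threshold = 100,
#'               tim4_threshold = 100))
#' det <- assignZones(det, sim$zones)
#' quantifyComposition(det)
#' @export
quantifyComposition <- function(detections) {
  stopifnot(is(detections, "CellDetections"))
  tb <- featureTable(detections)
  if (!all(c("class", "zone") %in% names(tb)))
    stop("class and zone columns are required; run classifyCells and assignZones",
         call. = FALSE)
  id <- imageId(detections)
  nExcl <- sum(tb$zone == "excluded")
  kept <- tb[tb$zone != "excluded", , drop = FALSE]
  nTot <- nrow(kept)
  if (nTot == 0)
    warning("no non-excluded cells: all percentages are missing")
  rows <- list()
  for (cl in .macClasses) {
    nC <- sum(kept$class == cl)
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = id, zone = "all", class = cl, count = nC,
      pct_of_total_macs = if (nTot > 0) 100 * nC / nTot else NA_real_,
      pct_of_class_in_zone = NA_real_)
    for (z in c("Hi", "Lo")) {
      nCZ <- sum(kept$class == cl & kept$zone == z)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, zone = z, class = cl, count = nCZ,
        pct_of_total_macs = NA_real_,
        pct_of_class_in_zone = if (nC > 0) 100 * nCZ / nC else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  out$n_excluded_cells <- nExcl
  out
}
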