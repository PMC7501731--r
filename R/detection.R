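# Tiled macrophage detection on the F4/80 channel: per-tile median filter
# and threshold, assembly of one full-size binary mask, then global
# connected-component labelling, hole filling and particle area filtering.
#
# Tiles are filtered with a halo of real image pixels of width equal to the
# median radius, so per-tile filtering equals whole-image filtering exactly
# and the detection set is invariant to the tile size (fixed or global Otsu
# thresholding; the per-tile Otsu mode intentionally reproduces
# tile-dependent behaviour and is exempt).

#' Detection parameters
#'
#' @param tile_size Tile edge length in pixels.
#' @param tile_overlap Extra tile overlap in pixels (overlapping results are
#'   combined by logical OR; the default 0 is lossless because tiles are
#'   filtered with a halo).
#' @param median_radius Radius of the disk-shaped median filter window in
#'   pixels (0 disables filtering).
#' @param threshold_mode One of \code{"fixed"}, \code{"global-otsu"},
#'   \code{"per-tile-otsu"}.
#' @param threshold_value Intensity threshold used in \code{"fixed"} mode;
#'   a pixel is foreground iff intensity >= threshold.
#' @param min_area Minimum particle area in pixels; components below it are
#'   removed, components at exactly \code{min_area} are retained.
#' @param fill_holes Fill holes inside components before area filtering.
#' @param object_connectivity 4 or 8 (background hole filling uses the
#'   complementary connectivity).
#' @return Validated parameter list.
#' @export
detectionParams <- function(tile_size = 256, tile_overlap = 0,
                            median_radius = 2,
                            threshold_mode = c("global-otsu", "fixed",
                                               "per-tile-otsu"),
                            threshold_value = 0,
                            min_area = 100, fill_holes = TRUE,
                            object_connectivity = 8) {
  threshold_mode <- match.arg(threshold_mode)
  p <- list(tile_size = as.integer(tile_size),
            tile_overlap = as.integer(tile_overlap),
            median_radius = as.integer(median_radius),
            threshold_mode = threshold_mode,
            threshold_value = threshold_value,
            min_area = as.integer(min_area),
            fill_holes = isTRUE(fill_holes),
            object_connectivity = as.integer(object_connectivity))
  stopifnot(p$tile_size > 2 * p$median_radius, p$min_area >= 1,
            p$threshold_value >= 0, p$median_radius >= 0,
            p$tile_overlap >= 0, p$object_connectivity %in% c(4L, 8L))
  p
}

#' Median-filter an intensity channel
#'
#' Disk-shaped window of the given radius (offsets with
#' \eqn{di^2 + dj^2 \le r^2}), edges handled by reflection; radius 0 is the
#' identity.
#'
#' @param channel Numeric matrix.
#' @param median_radius Window radius in pixels.
#' @return Filtered matrix of the same shape.
#' @export
medianFilterChannel <- function(channel, median_radius) {
  stopifnot(median_radius >= 0)
  if (median_radius == 0) return(channel)
  off <- ballOffsets(median_radius)[, 1:2]
  off <- unique(off)
  .cpp_median_filter(channel, .offsets3(off)[, 1:2, drop = FALSE])
}

#' Threshold a filtered channel
#'
#' Foreground iff intensity >= threshold. \code{"fixed"} uses
#' \code{threshold_value}; \code{"global-otsu"} derives one threshold from
#' the whole image; \code{"per-tile-otsu"} is applied per tile by
#' \code{\link{detectMacrophages}} (calling it here computes a global Otsu
#' threshold as well). A constant image under an Otsu mode yields an
#' all-background mask with a warning.
#'
#' @param filtered Numeric matrix (typically median-filtered).
#' @param params \code{\link{detectionParams}}.
#' @return Logical matrix.
#' @export
thresholdChannel <- function(filtered, params = detectionParams()) {
  mode <- params$threshold_mode
  if (mode == "fixed") return(filtered >= params$threshold_value)
  t <- .otsuThreshold(filtered)
  if (is.na(t)) {
    warning("constant image: Otsu threshold undefined, returning all-background")
    return(matrix(FALSE, nrow(filtered), ncol(filtered)))
  }
  filtered >= t
}

# tile origin grid along one axis
.tileStarts <- function(n, size, overlap) {
  step <- max(1L, size - overlap)
  s <- seq(1L, n, by = step)
  s[s <= n]
}

# median-filter the full channel tile by tile with a real-pixel halo;
# identical to whole-image filtering for any tile size
.tiledMedian <- function(channel, tile_size, tile_overlap, radius) {
  nr <- nrow(channel); nc <- ncol(channel)
  if (radius == 0) return(channel)
  out <- matrix(0, nr, nc)
  for (r0 in .tileStarts(nr, tile_size, tile_overlap)) {
    r1 <- min(nr, r0 + tile_size - 1L)
    for (c0 in .tileStarts(nc, tile_size, tile_overlap)) {
      c1 <- min(nc, c0 + tile_size - 1L)
      hr0 <- max(1L, r0 - radius); hr1 <- min(nr, r1 + radius)
      hc0 <- max(1L, c0 - radius); hc1 <- min(nc, c1 + radius)
      f <- medianFilterChannel(channel[hr0:hr1, hc0:hc1, drop = FALSE], radius)
      out[r0:r1, c0:c1] <- f[(r0 - hr0 + 1L):(r1 - hr0 + 1L),
                             (c0 - hc0 + 1L):(c1 - hc0 + 1L)]
    }
  }
  out
}

#' Detect F4/80-positive macrophages
#'
#' The full detection stage: per-tile median filter (with halo) on the F4/80
#' channel, thresholding (fixed / global Otsu / per-tile Otsu), assembly of
#' one full-size binary mask (overlaps combined by OR), global
#' connected-component labelling, hole filling and removal of components
#' smaller than \code{min_area}. Each surviving component becomes one
#' detection; detections are pairwise disjoint. Cells touching the image
#' border are retained and flagged.
#'
#' @param image A \linkS4class{MultiplexImage} containing an F4/80 channel.
#' @param params \code{\link{detectionParams}}.
#' @return A \linkS4class{CellDetections}.
#' @examples
#' sim <- generateTissueImage(tissueSpec(imageShape = c(256, 256),
#'   nCells = c(ResKC = 8, moKC = 4, C4negMac = 4, distractor = 2),
#'   nHiPatches = 0, nVessels = 0, noiseSd = 0, seed = 2))
#' det <- detectMacrophages(sim$image,
#'   detectionParams(threshold_mode = "fixed", threshold_value = 100,
#'                   min_area = 10))
#' nDetections(det)
#' @export
detectMacrophages <- function(image, params = detectionParams()) {
  stopifnot(is(image, "MultiplexImage"))
  channel <- getChannel(image, "F4/80")
  nr <- nrow(channel); nc <- ncol(channel)
  ts <- min(params$tile_size, max(nr, nc))

  filtered <- .tiledMedian(channel, ts, params$tile_overlap,
                           params$median_radius)
  mode <- params$threshold_mode
  if (mode == "per-tile-otsu") {
    mask <- matrix(FALSE, nr, nc)
    for (r0 in .tileStarts(nr, ts, params$tile_overlap)) {
      r1 <- min(nr, r0 + ts - 1L)
      for (c0 in .tileStarts(nc, ts, params$tile_overlap)) {
        c1 <- min(nc, c0 + ts - 1L)
        tile <- filtered[r0:r1, c0:c1, drop = FALSE]
        t <- .otsuThreshold(tile)
        if (!is.na(t))
          mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | (tile >= t)
      }
    }
  } else {
    mask <- thresholdChannel(filtered, params)
  }

  if (params$fill_holes) mask <- fillHoles(mask, params$object_connectivity)
  lab <- labelComponents(mask, connectivity = params$object_connectivity)

  n <- max(lab)
  if (n == 0)
    return(CellDetections(matrix(0L, nr, nc), pixelSize = pixelSize(image),
                          imageId = imageId(image)))
  areas <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(areas >= params$min_area)
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]
  if (!length(keep))
    return(CellDetections(matrix(0L, nr, nc), pixelSize = pixelSize(image),
                          imageId = imageId(image)))

  detectionsFromLabels(lab, pixelSize = pixelSize(image),
                       imageId = imageId(image))
}

#' Build a CellDetections object from a label image
#'
#' Computes the per-cell table (centroid, area in pixels and um^2, border
#' flag) from an integer label image, e.g. one re-read from disk. Labels
#' must be contiguous from 1.
#'
#' @param labels Integer label matrix (0 = background).
#' @param pixelSize Micrometres per pixel.
#' @param imageId Source image identifier.
#' @return A \linkS4class{CellDetections}.
#' @export
detectionsFromLabels <- function(labels, pixelSize = 1, imageId = "image") {
  storage.mode(labels) <- "integer"
  nr <- nrow(labels); nc <- ncol(labels)
  n <- max(labels, 0L)
  if (n == 0)
    return(CellDetections(labels, pixelSize = pixelSize, imageId = imageId))
  px <- which(labels > 0, arr.ind = TRUE)
  ids <- labels[px]
  cr <- vapply(split(px[, 1], ids), mean, numeric(1))
  cc <- vapply(split(px[, 2], ids), mean, numeric(1))
  area <- as.integer(tabulate(ids, nbins = n))
  border <- px[, 1] == 1L | px[, 1] == nr | px[, 2] == 1L | px[, 2] == nc
  touches <- vapply(split(border, ids), any, logical(1))
  tb <- data.frame(cell_id = seq_len(n),
                   centroid_row = unname(cr), centroid_col = unname(cc),
                   area_px = area,
                   area_um2 = area * pixelSize^2,
                   touches_border = unname(touches))
  CellDetections(labels, tb, pixelSize = pixelSize, imageId = imageId)
}
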