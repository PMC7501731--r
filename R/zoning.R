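# Desmin-high / Desmin-low tissue zoning and large-vessel exclusion: a
# deterministic smooth -> threshold -> morphological clean pipeline in
# place of an interactively trained pixel classifier; a pre-computed zone
# or vessel mask can be supplied to bypass either stage.

#' Zoning parameters
#'
#' @param smoothing_sigma Gaussian smoothing sigma in pixels applied to the
#'   Desmin channel (0 disables smoothing).
#' @param threshold_mode \code{"otsu"}, \code{"quantile"} or \code{"fixed"}.
#' @param threshold_value Intensity cut for \code{"fixed"} mode.
#' @param quantile_level Quantile in (0, 1) for \code{"quantile"} mode.
#' @param min_hi_area Minimum Desmin-high component area in um^2; smaller
#'   components are relabelled Desmin-low.
#' @param closing_radius Disk radius (pixels) of the morphological closing
#'   applied to the high mask, also used as the dilation radius of the
#'   automatic vessel mask.
#' @param vessel_high_quantile Quantile defining "co-high" Desmin and CD31
#'   pixels for \code{\link{autoVesselMask}}.
#' @param vessel_min_area Minimum vessel component area in um^2.
#' @return Validated parameter list.
#' @export
zoneParams <- function(smoothing_sigma = 4,
                       threshold_mode = c("otsu", "quantile", "fixed"),
                       threshold_value = 0, quantile_level = 0.75,
                       min_hi_area = 500, closing_radius = 3,
                       vessel_high_quantile = 0.99, vessel_min_area = 200) {
  threshold_mode <- match.arg(threshold_mode)
  p <- list(smoothing_sigma = smoothing_sigma,
            threshold_mode = threshold_mode,
            threshold_value = threshold_value,
            quantile_level = quantile_level,
            min_hi_area = min_hi_area, closing_radius = as.integer(closing_radius),
            vessel_high_quantile = vessel_high_quantile,
            vessel_min_area = vessel_min_area)
  stopifnot(p$smoothing_sigma >= 0, p$min_hi_area >= 0,
            p$vessel_min_area >= 0, p$closing_radius >= 0,
            p$quantile_level > 0, p$quantile_level < 1,
            p$vessel_high_quantile > 0, p$vessel_high_quantile < 1)
  p
}

.diskBrush <- function(radius) {
  if (radius == 0) return(matrix(1, 1, 1))
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' Segment Desmin-high and Desmin-low zones
#'
#' Gaussian smoothing of the Desmin channel, intensity threshold, disk
#' closing of the high mask, and relabelling of high components smaller
#' than \code{min_hi_area} as low. Deterministic. Vessel exclusion is a
#' separate step (\code{\link{applyVesselExclusion}}).
#'
#' @param image A \linkS4class{MultiplexImage} with a Desmin channel.
#' @param params \code{\link{zoneParams}}.
#' @return A \linkS4class{ZoneMap} with labels 1 (low) and 2 (high).
#' @export
segmentDesminZones <- function(image, params = zoneParams()) {
  stopifnot(is(image, "MultiplexImage"))
  desmin <- getChannel(image, "Desmin")
  sm <- desmin
  if (params$smoothing_sigma > 0)
    sm <- as.matrix(EBImage::gblur(EBImage::Image(desmin),
                                   sigma = params$smoothing_sigma))
  # Otsu is computed on intensities winsorized at vessel_high_quantile:
  # large-vessel pixels are rare, very bright outliers that would otherwise
  # dominate the between-class variance; they are handled by the separate
  # vessel-exclusion step.
  t <- switch(params$threshold_mode,
              "fixed" = params$threshold_value,
              "quantile" = unname(quantile(sm, params$quantile_level)),
              "otsu" = .otsuThreshold(pmin(sm,
                quantile(sm, params$vessel_high_quantile))))
  if (is.na(t)) {
    warning("constant Desmin channel: whole image labelled Desmin-low")
    return(ZoneMap(matrix(1L, nrow(desmin), ncol(desmin)),
                   pixelSize = pixelSize(image)))
  }
  hi <- sm >= t
  if (params$closing_radius > 0 && any(hi)) {
    hi <- as.matrix(EBImage::closing(EBImage::Image(hi * 1),
                                     .diskBrush(params$closing_radius))) > 0.5
  }
  # drop small high components
  if (any(hi)) {
    lab <- labelComponents(hi, connectivity = 8)
    areas <- tabulate(lab[lab > 0], nbins = max(lab)) * pixelSize(image)^2
    small <- which(areas < params$min_hi_area)
    if (length(small)) hi[lab %in% small] <- FALSE
  }
  labels <- matrix(1L, nrow(desmin), ncol(desmin))
  labels[hi] <- 2L
  ZoneMap(labels, pixelSize = pixelSize(image))
}

#' Exclude vessel regions from a zone map
#'
#' Pixels in the vessel mask receive label 0 (excluded) regardless of their
#' prior zone; zone areas follow from the new labels. An empty mask leaves
#' the map unchanged.
#'
#' @param zonemap A \linkS4class{ZoneMap}.
#' @param vessel_mask Logical matrix of the same shape.
#' @return The updated \linkS4class{ZoneMap}.
#' @export
applyVesselExclusion <- function(zonemap, vessel_mask) {
  stopifnot(is(zonemap, "ZoneMap"))
  lab <- zoneLabels(zonemap)
  if (!identical(dim(lab), dim(vessel_mask)))
    stop("vessel mask shape does not match the zone map", call. = FALSE)
  lab[vessel_mask > 0] <- 0L
  ZoneMap(lab, pixelSize = pixelSize(zonemap))
}

#' Automatic large-vessel mask (experimental)
#'
#' Automates the manual vessel call: pixels above
#' \code{vessel_high_quantile} in BOTH the Desmin and CD31 channels, dilated
#' by \code{closing_radius}, with components smaller than
#' \code{vessel_min_area} dropped. Manual vessel annotation is the
#' reference workflow; this convenience is logged as experimental and the
#' external mask remains the default route.
#'
#' @param image A \linkS4class{MultiplexImage} with Desmin and CD31.
#' @param params \code{\link{zoneParams}}.
#' @return Logical vessel mask.
#' @export
autoVesselMask <- function(image, params = zoneParams()) {
  stopifnot(is(image, "MultiplexImage"))
  message("autoVesselMask is experimental; manual masks are the reference workflow")
  desmin <- getChannel(image, "Desmin")
  cd31 <- getChannel(image, "CD31")
  q <- params$vessel_high_quantile
  # a channel without dynamic range has no "high" pixels
  high <- function(m) if (max(m) > min(m)) m >= quantile(m, q)
    else matrix(FALSE, nrow(m), ncol(m))
  mask <- high(desmin) & high(cd31)
  if (any(mask) && params$closing_radius > 0) {
    mask <- as.matrix(EBImage::dilate(EBImage::Image(mask * 1),
                                      .diskBrush(params$closing_radius))) > 0.5
  }
  if (any(mask)) {
    lab <- labelComponents(mask, connectivity = 8)
    areas <- tabulate(lab[lab > 0], nbins = max(lab)) * pixelSize(image)^2
    small <- which(areas < params$vessel_min_area)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  dim(mask) <- dim(desmin)
  mask
}
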