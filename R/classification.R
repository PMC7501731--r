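# Per-cell marker intensities and subset calls. The gate mirrors the
# flow-cytometry hierarchy: F4/80+ detections are split on CLEC4F first,
# and TIM4 status is only evaluated for CLEC4F-positive cells:
#   CLEC4F+ TIM4+  -> ResKC   (embryonically seeded resident Kupffer cell)
#   CLEC4F+ TIM4-  -> moKC    (monocyte-derived Kupffer cell)
#   CLEC4F-        -> C4negMac (recruited CLEC4F- macrophage)

#' Classification parameters
#'
#' @param threshold_mode How marker positivity thresholds are derived:
#'   \code{"otsu-on-cell-means"} (1D Otsu over the per-cell mean
#'   intensities, per marker), \code{"fixed"} (use the values below) or
#'   \code{"quantile"} (per-marker quantile of cell means).
#' @param clec4f_threshold,tim4_threshold Fixed intensity thresholds
#'   (\code{"fixed"} mode). A cell whose mean equals the threshold is
#'   positive (>= convention).
#' @param quantile_level Quantile in (0, 1) for \code{"quantile"} mode.
#' @param feature_stat Per-cell feature statistic, \code{"mean"} (default)
#'   or \code{"median"}.
#' @return Validated parameter list.
#' @export
classParams <- function(threshold_mode = c("otsu-on-cell-means", "fixed",
                                           "quantile"),
                        clec4f_threshold = 0, tim4_threshold = 0,
                        quantile_level = 0.5,
                        feature_stat = c("mean", "median")) {
  threshold_mode <- match.arg(threshold_mode)
  feature_stat <- match.arg(feature_stat)
  p <- list(threshold_mode = threshold_mode,
            clec4f_threshold = clec4f_threshold,
            tim4_threshold = tim4_threshold,
            quantile_level = quantile_level,
            feature_stat = feature_stat)
  stopifnot(p$clec4f_threshold >= 0, p$tim4_threshold >= 0,
            p$quantile_level > 0, p$quantile_level < 1)
  p
}

#' Feature-table column name for a channel
#'
#' Maps a channel name to its per-cell mean-intensity column in the feature
#' table: \code{"F4/80"} becomes \code{"mean_F480"}, etc.
#'
#' @param channel Channel name.
#' @return Column name string.
#' @export
featureColumn <- function(channel) {
  paste0("mean_", gsub("[^A-Za-z0-9]", "", channel))
}

#' Extract per-cell marker features
#'
#' Adds one column per image channel holding the arithmetic mean (or
#' median, per \code{feature_stat}) of that channel over each detection
#' mask. Order-independent: features depend only on the mask and the image.
#'
#' @param detections A \linkS4class{CellDetections} from the same image.
#' @param image The source \linkS4class{MultiplexImage}.
#' @param params \code{\link{classParams}} (only \code{feature_stat} is
#'   used here).
#' @return The \linkS4class{CellDetections} with feature columns added.
#' @export
extractFeatures <- function(detections, image, params = classParams()) {
  stopifnot(is(detections, "CellDetections"), is(image, "MultiplexImage"))
  lab <- labelImage(detections)
  ref <- getChannel(image, channelNames(image)[1])
  if (!identical(dim(lab), dim(ref)))
    stop("detections and image geometry differ", call. = FALSE)
  tb <- featureTable(detections)
  n <- nrow(tb)
  fg <- lab > 0
  ids <- lab[fg]
  statfun <- if (params$feature_stat == "median")
    function(v, g) vapply(split(v, g), median, numeric(1))
  else
    function(v, g) vapply(split(v, g), mean, numeric(1))
  for (cn in channelNames(image)) {
    col <- featureColumn(cn)
    if (n == 0) { tb[[col]] <- numeric(0); next }
    vals <- getChannel(image, cn)[fg]
    m <- statfun(vals, ids)
    tb[[col]] <- unname(m[as.character(tb$cell_id)])
  }
  detections@table <- tb
  validObject(detections)
  detections
}

# resolve a marker threshold from per-cell means
.markerThreshold <- function(values, params, fixed) {
  switch(params$threshold_mode,
         "fixed" = fixed,
         "quantile" = unname(quantile(values, params$quantile_level)),
         "otsu-on-cell-means" = {
           if (length(values) < 3)
             stop(paste("otsu-on-cell-means needs at least 3 cells;",
                        "use fixed thresholds"), call. = FALSE)
           t <- .otsu1d(values)
           if (is.na(t))
             stop(paste("cell means are constant; Otsu is undefined,",
                        "use fixed thresholds"), call. = FALSE)
           t
         })
}

#' Classify detected macrophages into subsets
#'
#' Hierarchical marker gate on per-cell CLEC4F and TIM4 means (>= threshold
#' counts as positive): CLEC4F+TIM4+ ResKC, CLEC4F+TIM4- moKC, CLEC4F-
#' C4negMac. Every cell receives exactly one label.
#'
#' @param detections A \linkS4class{CellDetections} with extracted features
#'   (see \code{\link{extractFeatures}}).
#' @param params \code{\link{classParams}}.
#' @return The \linkS4class{CellDetections} with a \code{class} column;
#'   the resolved thresholds are attached as attribute
#'   \code{"thresholds"} of the table.
#' @export
classifyCells <- function(detections, params = classParams()) {
  stopifnot(is(detections, "CellDetections"))
  tb <- featureTable(detections)
  cC4 <- featureColumn("CLEC4F")
  cT4 <- featureColumn("TIM4")
  if (!all(c(cC4, cT4) %in% names(tb)))
    stop("CLEC4F and TIM4 features are required; run extractFeatures first",
         call. = FALSE)
  if (nrow(tb) == 0) {
    tb$class <- character(0)
    detections@table <- tb
    return(detections)
  }
  thC4 <- .markerThreshold(tb[[cC4]], params, params$clec4f_threshold)
  thT4 <- .markerThreshold(tb[[cT4]], params, params$tim4_threshold)
  c4pos <- tb[[cC4]] >= thC4
  t4pos <- tb[[cT4]] >= thT4
  cls <- ifelse(c4pos, ifelse(t4pos, "ResKC", "moKC"), "C4negMac")
  tb$class <- cls
  attr(tb, "thresholds") <- c(CLEC4F = thC4, TIM4 = thT4)
  detections@table <- tb
  validObject(detections)
  detections
}
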