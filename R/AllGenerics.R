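#' @name accessors
#' @title Accessors for macquant classes
#' @description Slot access for the S4 containers goes through these
#'   accessors; slots are an implementation detail.
#' @param x An object.
#' @param name Channel name (aliases such as \code{"F4-80"} resolve to the
#'   stored \code{"F4/80"}).
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @rdname accessors
#' @export
setGeneric("zoneLabels", function(x) standardGeneric("zoneLabels"))
#' @rdname accessors
#' @export
setGeneric("zoneAreas", function(x) standardGeneric("zoneAreas"))
#' @rdname accessors
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))
#' @rdname accessors
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))
#' @rdname accessors
#' @export
setGeneric("nDetections", function(x) standardGeneric("nDetections"))
#' @rdname accessors
#' @export
setGeneric("componentVolumes", function(x) standardGeneric("componentVolumes"))
#' @rdname accessors
#' @export
setGeneric("totalVolume", function(x, ...) standardGeneric("totalVolume"))

#' @rdname accessors
#' @export
setMethod("channelNames", "MultiplexImage", function(x) names(x@channels))

#' @rdname accessors
#' @export
setMethod("getChannel", "MultiplexImage", function(x, name) {
  stored <- names(x@channels)
  hit <- match(.channelKey(name), .channelKey(stored))
  if (is.na(hit))
    stop(sprintf("channel '%s' not found; available channels: %s",
                 name, paste(stored, collapse = ", ")), call. = FALSE)
  x@channels[[hit]]
})

#' @rdname accessors
#' @export
setMethod("pixelSize", "MultiplexImage", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "ZoneMap", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "CellDetections", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("imageId", "MultiplexImage", function(x) x@imageId)
#' @rdname accessors
#' @export
setMethod("imageId", "CellDetections", function(x) x@imageId)

#' @rdname accessors
#' @export
setMethod("zoneLabels", "ZoneMap", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("zoneAreas", "ZoneMap", function(x) {
  px2 <- x@pixelSize^2
  lab <- x@labels
  c(excluded = sum(lab == 0L) * px2,
    low = sum(lab == 1L) * px2,
    high = sum(lab == 2L) * px2)
})

#' @rdname accessors
#' @export
setMethod("labelImage", "CellDetections", function(x) x@labelImage)
#' @rdname accessors
#' @export
setMethod("featureTable", "CellDetections", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("nDetections", "CellDetections", function(x) nrow(x@table))

#' @rdname accessors
#' @export
setMethod("componentVolumes", "DropletResult", function(x) {
  n <- length(x@componentVoxels)
  vox_um3 <- prod(x@voxelSize) / 1e9   # nm^3 -> um^3
  data.frame(component = seq_len(n),
             voxels = x@componentVoxels,
             volume_um3 = x@componentVoxels * vox_um3)
})

#' @rdname accessors
#' @param ... For \code{totalVolume}: \code{units}, one of \code{"voxels"}
#'   or \code{"um3"}.
#' @export
setMethod("totalVolume", "DropletResult", function(x, units = c("voxels", "um3")) {
  units <- match.arg(units)
  tot <- sum(x@componentVoxels)
  if (units == "voxels") tot else tot * prod(x@voxelSize) / 1e9
})

setMethod("show", "MultiplexImage", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("MultiplexImage '%s': %d x %d px (%.3g um/px)\n",
              object@imageId, d[1], d[2], object@pixelSize))
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
})

setMethod("show", "ZoneMap", function(object) {
  a <- zoneAreas(object)
  cat(sprintf("ZoneMap %d x %d px: high %.0f um2, low %.0f um2, excluded %.0f um2\n",
              nrow(object@labels), ncol(object@labels),
              a["high"], a["low"], a["excluded"]))
})

setMethod("show", "CellDetections", function(object) {
  cat(sprintf("CellDetections '%s': %d cells", object@imageId,
              nrow(object@table)))
  if ("class" %in% names(object@table) && nrow(object@table)) {
    tab <- table(object@table$class)
    cat(" (", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
})

setMethod("show", "DropletResult", function(object) {
  cat(sprintf("DropletResult: %d components, %d voxels, %.4g um3 total\n",
              length(object@componentVoxels),
              as.integer(sum(object@componentVoxels)),
              totalVolume(object, "um3")))
})
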