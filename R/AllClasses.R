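#' @useDynLib macquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats quantile rnorm runif median setNames
#' @importFrom utils read.csv write.csv
NULL

#' Canonical imaging channels
#'
#' The five channels the quantification pipeline understands: the
#' pan-macrophage detection marker F4/80, the Kupffer-cell markers CLEC4F and
#' TIM4, the stellate-cell / fibrosis marker Desmin and the endothelial
#' marker CD31.
#'
#' @return Character vector of canonical channel names.
#' @export
canonicalChannels <- function() c("F4/80", "CLEC4F", "TIM4", "Desmin", "CD31")

# channel-name normalisation: case-insensitive, punctuation-insensitive, so
# "F4-80", "f4/80" and "F480" all resolve to the stored "F4/80".
.channelKey <- function(x) tolower(gsub("[^a-zA-Z0-9]", "", x))

#' MultiplexImage: named 2D intensity channels sharing one geometry
#'
#' Container for a multi-channel immunofluorescence field of view. All
#' channels are numeric matrices of identical dimensions holding non-negative
#' intensities; physical scale is carried as micrometres per pixel.
#'
#' @slot channels Named list of numeric matrices (one per channel).
#' @slot pixelSize Numeric scalar, micrometres per pixel (> 0).
#' @slot imageId Character scalar identifying the field of view.
#' @export
setClass("MultiplexImage",
  representation(channels = "list", pixelSize = "numeric",
                 imageId = "character"),
  validity = function(object) {
    ch <- object@channels
    if (length(ch) == 0) return("at least one channel is required")
    if (is.null(names(ch)) || any(!nzchar(names(ch))))
      return("channels must be named")
    if (anyDuplicated(.channelKey(names(ch))))
      return("channel names must be unique after normalisation")
    if (!all(vapply(ch, is.matrix, logical(1))))
      return("every channel must be a 2D matrix")
    dims <- vapply(ch, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      return("all channels must share identical dimensions")
    if (any(vapply(ch, function(m) any(m < 0), logical(1))))
      return("channel intensities must be non-negative")
    if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
      return("pixelSize must be a single positive number")
    TRUE
  })

#' Construct a MultiplexImage
#'
#' @param channels Named list of numeric matrices with identical dimensions.
#' @param pixelSize Micrometres per pixel.
#' @param imageId Identifier string.
#' @return A \linkS4class{MultiplexImage}.
#' @examples
#' img <- MultiplexImage(list("F4/80" = matrix(0, 8, 8)), pixelSize = 0.5)
#' channelNames(img)
#' @export
MultiplexImage <- function(channels, pixelSize = 1, imageId = "image") {
  channels <- lapply(channels, function(m) {
    if (!is.matrix(m)) m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  new("MultiplexImage", channels = channels, pixelSize = as.numeric(pixelSize),
      imageId = as.character(imageId))
}

#' ZoneMap: per-pixel tissue partition
#'
#' Label image partitioning the tissue into excluded/vessel (0), Desmin-low
#' (1) and Desmin-high (2) pixels. Every pixel carries exactly one label, so
#' zone areas always sum to the image area.
#'
#' @slot labels Integer matrix with values in {0, 1, 2}.
#' @slot pixelSize Micrometres per pixel.
#' @export
setClass("ZoneMap",
  representation(labels = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    if (!all(object@labels %in% 0:2))
      return("zone labels must be 0 (excluded), 1 (low) or 2 (high)")
    if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
      return("pixelSize must be a single positive number")
    TRUE
  })

#' Construct a ZoneMap
#'
#' @param labels Integer matrix of zone labels (0 excluded, 1 low, 2 high).
#' @param pixelSize Micrometres per pixel.
#' @return A \linkS4class{ZoneMap}.
#' @export
ZoneMap <- function(labels, pixelSize = 1) {
  storage.mode(labels) <- "integer"
  new("ZoneMap", labels = labels, pixelSize = as.numeric(pixelSize))
}

#' CellDetections: labelled macrophage detections with per-cell features
#'
#' Holds the integer label image (pixel value = cell_id, 0 = background) and
#' the per-cell feature table produced by detection and enriched by feature
#' extraction, classification and zone assignment.
#'
#' @slot labelImage Integer matrix; 0 background, k > 0 the mask of cell k.
#' @slot table data.frame with one row per detection (cell_id, centroid_row,
#'   centroid_col, area_px, area_um2, touches_border, then per-channel means,
#'   class and zone columns as they are filled in).
#' @slot pixelSize Micrometres per pixel.
#' @slot imageId Identifier of the source image.
#' @export
setClass("CellDetections",
  representation(labelImage = "matrix", table = "data.frame",
                 pixelSize = "numeric", imageId = "character"),
  validity = function(object) {
    tb <- object@table
    need <- c("cell_id", "centroid_row", "centroid_col", "area_px",
              "area_um2", "touches_border")
    if (!all(need %in% names(tb)))
      return(paste("table must contain columns:", paste(need, collapse = ", ")))
    lab <- object@labelImage
    ids <- sort(unique(as.vector(lab[lab > 0])))
    if (nrow(tb) && !identical(as.integer(sort(tb$cell_id)), as.integer(ids)))
      return("table cell_ids must match label image values")
    TRUE
  })

.emptyDetectionTable <- function() {
  data.frame(cell_id = integer(0), centroid_row = numeric(0),
             centroid_col = numeric(0), area_px = integer(0),
             area_um2 = numeric(0), touches_border = logical(0))
}

#' Construct a CellDetections object
#'
#' @param labelImage Integer label matrix (0 = background).
#' @param table Per-cell feature data.frame.
#' @param pixelSize Micrometres per pixel.
#' @param imageId Source image identifier.
#' @return A \linkS4class{CellDetections}.
#' @export
CellDetections <- function(labelImage, table = .emptyDetectionTable(),
                           pixelSize = 1, imageId = "image") {
  storage.mode(labelImage) <- "integer"
  new("CellDetections", labelImage = labelImage, table = table,
      pixelSize = as.numeric(pixelSize), imageId = as.character(imageId))
}

#' DropletResult: labelled lipid-droplet volume with component volumes
#'
#' Output of the droplet post-processing pipeline: the labelled 3D volume
#' after threshold, small-component removal and spherical opening, with
#' per-component voxel counts and physical volumes.
#'
#' @slot labels Integer 3D array; 0 background, labels contiguous from 1.
#' @slot componentVoxels Numeric vector of per-component voxel counts.
#' @slot voxelSize Numeric length-3 voxel edge lengths in nm (axis order of
#'   the array dimensions).
#' @export
setClass("DropletResult",
  representation(labels = "array", componentVoxels = "numeric",
                 voxelSize = "numeric"),
  validity = function(object) {
    if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
      return("voxelSize must be three positive nm values")
    nlab <- if (length(object@labels)) max(object@labels) else 0
    if (nlab != length(object@componentVoxels))
      return("componentVoxels must have one entry per label")
    TRUE
  })

#' @rdname DropletResult-class
#' @param labels Integer 3D label array.
#' @param componentVoxels Per-component voxel counts.
#' @param voxelSize Voxel edge lengths in nm.
#' @return A \linkS4class{DropletResult}.
#' @export
DropletResult <- function(labels, componentVoxels, voxelSize = c(5, 5, 5)) {
  storage.mode(labels) <- "integer"
  new("DropletResult", labels = labels,
      componentVoxels = as.numeric(componentVoxels),
      voxelSize = as.numeric(voxelSize))
}
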