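# Low-level binary morphology shared by the 2D detection/zoning stages and
# the 3D droplet pipeline. Volumes are base R logical/integer arrays in
# column-major layout; a 2D image is a degenerate volume with third dim 1.

# neighbourhood offsets for connected-component labelling
.connOffsets <- function(connectivity, ndim) {
  if (ndim == 2) {
    if (!connectivity %in% c(4, 8))
      stop("2D connectivity must be 4 or 8", call. = FALSE)
    g <- expand.grid(di = -1:1, dj = -1:1, dk = 0L)
    g <- g[!(g$di == 0 & g$dj == 0), ]
    if (connectivity == 4) g <- g[abs(g$di) + abs(g$dj) == 1, ]
  } else {
    if (!connectivity %in% c(6, 18, 26))
      stop("3D connectivity must be 6, 18 or 26", call. = FALSE)
    g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
    g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
    l1 <- abs(g$di) + abs(g$dj) + abs(g$dk)
    if (connectivity == 6) g <- g[l1 == 1, ]
    if (connectivity == 18) g <- g[l1 <= 2, ]
  }
  as.matrix(g)
}

#' Digital Euclidean ball offsets
#'
#' Lattice offsets of the digital Euclidean ball
#' \eqn{\{v : \lVert v \circ s\rVert_2 \le r\}} used as the "spherical"
#' structuring element of the droplet opening, optionally anisotropic via
#' per-axis spacings \code{s}.
#'
#' @param radius Ball radius in voxel units (>= 0).
#' @param spacing Per-axis physical spacing used to make the element
#'   anisotropic; default \code{c(1, 1, 1)} (isotropic, radius in voxels).
#' @return Integer matrix of (di, dj, dk) offsets including the origin.
#' @export
ballOffsets <- function(radius, spacing = c(1, 1, 1)) {
  stopifnot(radius >= 0, length(spacing) == 3, all(spacing > 0))
  rng <- lapply(spacing, function(s) seq(-floor(radius / s), floor(radius / s)))
  g <- expand.grid(di = rng[[1]], dj = rng[[2]], dk = rng[[3]])
  keep <- (g$di * spacing[1])^2 + (g$dj * spacing[2])^2 +
    (g$dk * spacing[3])^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

.as3d <- function(x) {
  if (is.null(dim(x)) || length(dim(x)) == 2) {
    array(x, dim = c(dim(as.matrix(x)), 1L))
  } else x
}

.offsets3 <- function(off) {
  off <- as.matrix(off)
  storage.mode(off) <- "integer"
  if (ncol(off) == 2) off <- cbind(off, 0L)
  off
}

#' Label connected components
#'
#' Connected-component labelling of a binary image (connectivity 4/8) or
#' volume (connectivity 6/18/26). Labels are contiguous from 1 in raster
#' order of first encounter.
#'
#' @param mask Logical (or 0/1) matrix or 3D array.
#' @param connectivity 4 or 8 for 2D input; 6, 18 or 26 for 3D input.
#' @return Integer array of the same shape; 0 is background.
#' @export
labelComponents <- function(mask, connectivity = if (length(dim(mask)) == 3) 26 else 8) {
  dm <- dim(as.array(mask))
  ndim <- length(dm)
  off <- .offsets3(.connOffsets(connectivity, if (ndim == 3) 3 else 2))
  v <- .as3d(mask)
  lab <- .cpp_label_components(as.logical(v), as.integer(dim(v)), off)
  array(lab, dim = dm)
}

# erosion / dilation / opening with an explicit offset structuring element
.binErode <- function(mask, offsets) {
  dm <- dim(as.array(mask))
  v <- .as3d(mask)
  out <- .cpp_binary_erode(as.logical(v), as.integer(dim(v)), .offsets3(offsets))
  array(out, dim = dm)
}

.binDilate <- function(mask, offsets) {
  dm <- dim(as.array(mask))
  v <- .as3d(mask)
  out <- .cpp_binary_dilate(as.logical(v), as.integer(dim(v)), .offsets3(offsets))
  array(out, dim = dm)
}

#' Fill holes in a binary image
#'
#' Background components not connected to the image border are converted to
#' foreground. The background is traversed with the complementary
#' connectivity of the objects (8-connected objects imply 4-connected
#' background and vice versa), the standard digital-topology pairing.
#'
#' @param mask Logical matrix.
#' @param object_connectivity 4 or 8 (connectivity used for the objects).
#' @return Logical matrix with holes filled.
#' @export
fillHoles <- function(mask, object_connectivity = 8) {
  bg_conn <- if (object_connectivity == 8) 4 else 8
  bg <- labelComponents(!mask, connectivity = bg_conn)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  hole <- bg > 0 & !(bg %in% border)
  out <- mask | hole
  dim(out) <- dim(mask)
  out
}

# Otsu threshold of an intensity matrix via EBImage (256 bins over the data
# range). Returns NA for a constant image.
.otsuThreshold <- function(m) {
  r <- range(m)
  if (r[1] == r[2]) return(NA_real_)
  EBImage::otsu(EBImage::Image(m), range = r, levels = 256L)
}

# 1D Otsu on a vector of per-cell means (classification thresholds):
# exhaustive scan over midpoints between consecutive sorted unique values,
# maximising between-class variance.
.otsu1d <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2) return(NA_real_)
  cand <- (u[-1] + u[-length(u)]) / 2
  n <- length(x)
  bcv <- vapply(cand, function(t) {
    lo <- x < t
    n0 <- sum(lo)
    if (n0 == 0 || n0 == n) return(-Inf)
    w0 <- n0 / n
    w0 * (1 - w0) * (mean(x[lo]) - mean(x[!lo]))^2
  }, numeric(1))
  cand[which.max(bcv)]
}
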