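# Synthetic multiplex-IF tissue fields and 3D droplet probability stacks
# with exact ground truth. The generator is the package's testbed: every
# downstream stage (detection, classification, zoning, quantification,
# droplet volumetry) is validated against the truth tables produced here.

#' Specification of a synthetic multiplex tissue image
#'
#' Describes a liver-like field of view: blob macrophages of three subsets
#' plus a non-macrophage distractor, Desmin-high patches (stellate-cell
#' activation zones) enriched for CLEC4F- macrophages, and large vessels
#' rendered as Desmin/CD31 co-positive rings with a signal-free lumen.
#'
#' @param imageShape (rows, cols) in pixels.
#' @param pixelSize Micrometres per pixel.
#' @param nCells Named counts for ResKC, moKC, C4negMac and distractor cells.
#' @param cellRadiusMean,cellRadiusSd Cell radius distribution in pixels.
#' @param intensityMatrix class x channel mean foreground intensity (added on
#'   top of background inside each cell disk); rows ResKC, moKC, C4negMac,
#'   distractor; columns the \code{\link{canonicalChannels}}. The distractor
#'   row keeps F4/80 at background so it is invisible to detection.
#' @param backgroundLevel Per-channel baseline intensity.
#' @param noiseSd Additive Gaussian noise sd (clipped at 0).
#' @param nHiPatches Number of Desmin-high patches.
#' @param hiPatchRadius Patch radius in pixels.
#' @param enrichmentRho Ratio of CLEC4F- macrophage placement density in
#'   Desmin-high vs Desmin-low tissue (>= 0; 1 = no enrichment).
#' @param desminHiGain Multiplicative Desmin elevation inside patches.
#' @param nVessels Number of large vessels.
#' @param vesselRadius Outer vessel radius in pixels (ring width is a quarter
#'   of the radius; the lumen is signal-free).
#' @param vesselIntensity Intensity added to Desmin and CD31 on vessel rings.
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#' @return A validated spec (classed list) for
#'   \code{\link{generateTissueImage}}.
#' @export
tissueSpec <- function(imageShape = c(1024, 1024),
                       pixelSize = 0.5,
                       nCells = c(ResKC = 200, moKC = 150, C4negMac = 150,
                                  distractor = 50),
                       cellRadiusMean = 6, cellRadiusSd = 1,
                       intensityMatrix = NULL,
                       backgroundLevel = rep(10, 5),
                       noiseSd = 5,
                       nHiPatches = 4, hiPatchRadius = 120,
                       enrichmentRho = 4, desminHiGain = 3,
                       nVessels = 3, vesselRadius = 45,
                       vesselIntensity = 200,
                       seed = 1L) {
  ch <- canonicalChannels()
  cls <- c("ResKC", "moKC", "C4negMac", "distractor")
  if (is.null(intensityMatrix)) {
    intensityMatrix <- matrix(0, 4, 5, dimnames = list(cls, ch))
    intensityMatrix["ResKC", c("F4/80", "CLEC4F", "TIM4")] <- 180
    intensityMatrix["moKC", c("F4/80", "CLEC4F")] <- 180
    intensityMatrix["C4negMac", "F4/80"] <- 180
    intensityMatrix["distractor", "TIM4"] <- 120
  }
  nCells <- unlist(nCells)[cls]
  names(nCells) <- cls
  nCells[is.na(nCells)] <- 0
  names(backgroundLevel) <- ch
  spec <- list(imageShape = as.integer(imageShape), pixelSize = pixelSize,
               nCells = nCells, cellRadiusMean = cellRadiusMean,
               cellRadiusSd = cellRadiusSd, intensityMatrix = intensityMatrix,
               backgroundLevel = backgroundLevel, noiseSd = noiseSd,
               nHiPatches = as.integer(nHiPatches),
               hiPatchRadius = hiPatchRadius,
               enrichmentRho = enrichmentRho, desminHiGain = desminHiGain,
               nVessels = as.integer(nVessels), vesselRadius = vesselRadius,
               vesselIntensity = vesselIntensity, seed = as.integer(seed))
  stopifnot(length(spec$imageShape) == 2, all(spec$imageShape > 0),
            spec$pixelSize > 0, all(spec$nCells >= 0),
            spec$cellRadiusMean > 0, spec$cellRadiusSd >= 0,
            spec$noiseSd >= 0, spec$enrichmentRho >= 0,
            spec$desminHiGain > 0, spec$hiPatchRadius > 0,
            spec$vesselRadius > 0, spec$nHiPatches >= 0, spec$nVessels >= 0)
  if (intensityMatrix["distractor", "F4/80"] != 0)
    stop("distractor cells must keep F4/80 at background", call. = FALSE)
  class(spec) <- "tissueSpec"
  spec
}

# squared distance of every pixel to a centre (rows r0, cols c0)
.dist2 <- function(nr, nc, r0, c0) {
  outer((seq_len(nr) - r0)^2, (seq_len(nc) - c0)^2, "+")
}

#' Generate a synthetic multiplex tissue image with ground truth
#'
#' Places vessels, Desmin-high patches and non-overlapping cell disks
#' (rejection sampling with bounded retries), renders the five canonical
#' channels as background + class-dependent disk intensities + additive
#' Gaussian noise (clipped at 0), and returns exact truth tables.
#' CLEC4F- macrophage placement density in Desmin-high vs Desmin-low tissue
#' follows \code{enrichmentRho}; all other classes are placed uniformly over
#' non-vessel tissue.
#'
#' @param spec A \code{\link{tissueSpec}}.
#' @return A list with elements \code{image} (\linkS4class{MultiplexImage}),
#'   \code{truth} (data.frame: cell_id, class, centroid_row, centroid_col,
#'   radius, zone), \code{zones} (truth \linkS4class{ZoneMap}: vessel disks 0,
#'   patches 2, rest 1) and \code{vesselMask} (logical matrix of the full
#'   vessel disks used for exclusion).
#' @examples
#' sim <- generateTissueImage(tissueSpec(imageShape = c(256, 256),
#'   nCells = c(ResKC = 10, moKC = 5, C4negMac = 5, distractor = 2),
#'   nHiPatches = 1, hiPatchRadius = 50, nVessels = 1, seed = 7))
#' table(sim$truth$class)
#' @export
generateTissueImage <- function(spec) {
  stopifnot(inherits(spec, "tissueSpec"))
  withr::with_seed(spec$seed, .generateTissue(spec))
}

.generateTissue <- function(spec) {
  nr <- spec$imageShape[1]; nc <- spec$imageShape[2]
  ch <- canonicalChannels()

  # vessels: full disk excluded, ring (outer quarter) carries signal
  vesselMask <- matrix(FALSE, nr, nc)
  ringMask <- matrix(FALSE, nr, nc)
  vr <- spec$vesselRadius
  for (v in seq_len(spec$nVessels)) {
    r0 <- runif(1, vr + 1, nr - vr)
    c0 <- runif(1, vr + 1, nc - vr)
    d2 <- .dist2(nr, nc, r0, c0)
    vesselMask <- vesselMask | d2 <= vr^2
    ringMask <- ringMask | (d2 <= vr^2 & d2 > (0.75 * vr)^2)
  }

  # Desmin-high patches (vessel pixels keep the vessel label)
  hiMask <- matrix(FALSE, nr, nc)
  pr <- spec$hiPatchRadius
  for (p in seq_len(spec$nHiPatches)) {
    r0 <- runif(1, 1, nr)
    c0 <- runif(1, 1, nc)
    hiMask <- hiMask | .dist2(nr, nc, r0, c0) <= pr^2
  }
  zoneTruth <- matrix(1L, nr, nc)
  zoneTruth[hiMask] <- 2L
  zoneTruth[vesselMask] <- 0L

  # cell placement: hard disks, rejection sampling with bounded retries
  classes <- rep(names(spec$nCells), times = spec$nCells)
  n <- length(classes)
  radii <- pmax(3, rnorm(n, spec$cellRadiusMean, spec$cellRadiusSd))
  cr <- numeric(n); cc <- numeric(n)
  aHi <- sum(zoneTruth == 2L); aLo <- sum(zoneTruth == 1L)
  pHi <- if (aHi + aLo > 0)
    spec$enrichmentRho * aHi / (spec$enrichmentRho * aHi + aLo) else 0
  maxTries <- 5000L
  placed <- 0L
  for (i in seq_len(n)) {
    ri <- radii[i]
    targetZone <- NA_integer_
    if (classes[i] == "C4negMac" && aHi > 0 && aLo > 0)
      targetZone <- if (runif(1) < pHi) 2L else 1L
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      y <- runif(1, ri + 1, nr - ri)
      x <- runif(1, ri + 1, nc - ri)
      if (vesselMask[round(y), round(x)]) next
      if (!is.na(targetZone) && zoneTruth[round(y), round(x)] != targetZone)
        next
      if (placed > 0) {
        # 2 px clearance between disks keeps rendered masks disconnected
        # under 8-connectivity, so detection counts are exact
        j <- seq_len(placed)
        if (any((cr[j] - y)^2 + (cc[j] - x)^2 < (radii[j] + ri + 2)^2)) next
      }
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf(paste0("cell placement failed after %d retries at cell ",
                          "%d of %d; the requested layout is too dense ",
                          "(achievable ",
                          "density here is roughly %d cells for this ",
                          "geometry)"), maxTries, i, n, placed), call. = FALSE)
    placed <- placed + 1L
    cr[i] <- y; cc[i] <- x
  }

  # render channels
  channels <- lapply(ch, function(cn)
    matrix(spec$backgroundLevel[[cn]], nr, nc))
  names(channels) <- ch
  channels[["Desmin"]][hiMask & !vesselMask] <-
    channels[["Desmin"]][hiMask & !vesselMask] * spec$desminHiGain
  channels[["Desmin"]][ringMask] <-
    channels[["Desmin"]][ringMask] + spec$vesselIntensity
  channels[["CD31"]][ringMask] <-
    channels[["CD31"]][ringMask] + spec$vesselIntensity
  for (i in seq_len(n)) {
    ri <- radii[i]
    rows <- max(1, floor(cr[i] - ri)):min(nr, ceiling(cr[i] + ri))
    cols <- max(1, floor(cc[i] - ri)):min(nc, ceiling(cc[i] + ri))
    d2 <- outer((rows - cr[i])^2, (cols - cc[i])^2, "+")
    disk <- d2 <= ri^2
    for (cn in ch) {
      gain <- spec$intensityMatrix[classes[i], cn]
      if (gain != 0) {
        sub <- channels[[cn]][rows, cols]
        sub[disk] <- sub[disk] + gain
        channels[[cn]][rows, cols] <- sub
      }
    }
  }
  if (spec$noiseSd > 0)
    channels <- lapply(channels, function(m)
      pmax(m + matrix(rnorm(nr * nc, 0, spec$noiseSd), nr, nc), 0))

  truth <- data.frame(
    cell_id = seq_len(n), class = classes,
    centroid_row = cr, centroid_col = cc, radius = radii,
    zone = c("excluded", "Lo", "Hi")[
      zoneTruth[cbind(pmin(nr, pmax(1, round(cr))),
                      pmin(nc, pmax(1, round(cc))))] + 1L],
    stringsAsFactors = FALSE)

  list(image = MultiplexImage(channels, pixelSize = spec$pixelSize,
                              imageId = sprintf("synthetic-%d", spec$seed)),
       truth = truth,
       zones = ZoneMap(zoneTruth, pixelSize = spec$pixelSize),
       vesselMask = vesselMask)
}

#' Specification of a synthetic 3D droplet probability stack
#'
#' Emulates the probability maps that a segmentation network would emit for
#' FIB-SEM lipid droplets: Gaussian-blurred binary spheres rescaled to peak
#' 1 plus additive noise, with exact per-droplet lattice volumes as truth.
#' Optional adversarial components are compact binary blocks of exactly
#' requested voxel counts, planted to probe the small-component filter.
#'
#' @param stackShape (d1, d2, d3) stack dimensions in voxels.
#' @param voxelSize Voxel edge lengths in nm per axis (the 5 nm default
#'   matches a FIB milling step of 5 nm sections).
#' @param nDroplets Number of droplets.
#' @param radiusMean,radiusSd Droplet radius distribution in voxels.
#' @param blurSigma Gaussian blur sigma in voxels (0 = crisp binary
#'   spheres). The 0.5 default gives a ~1-voxel boundary transition, as a
#'   well-trained segmentation network would emit, and keeps the 0.5 level
#'   set within the curvature term \eqn{\sigma^2 \kappa} (< 0.1 voxel) of
#'   the true sphere surface so that thresholding is volume-faithful.
#' @param noiseSd Additive noise sd (stack re-clipped to [0, 1]).
#' @param adversarialComponents Optional integer vector of exact voxel counts
#'   to plant as compact binary components, pairwise well separated.
#' @param seed Integer seed.
#' @return A validated spec for \code{\link{generateDropletStack}}.
#' @export
dropletSpec <- function(stackShape = c(64, 96, 96),
                        voxelSize = c(5, 5, 5),
                        nDroplets = 10,
                        radiusMean = 6, radiusSd = 1.5,
                        blurSigma = 0.5, noiseSd = 0.05,
                        adversarialComponents = NULL,
                        seed = 1L) {
  spec <- list(stackShape = as.integer(stackShape),
               voxelSize = as.numeric(voxelSize),
               nDroplets = as.integer(nDroplets),
               radiusMean = radiusMean, radiusSd = radiusSd,
               blurSigma = blurSigma, noiseSd = noiseSd,
               adversarialComponents = as.integer(adversarialComponents),
               seed = as.integer(seed))
  stopifnot(length(spec$stackShape) == 3, all(spec$stackShape > 0),
            length(spec$voxelSize) == 3, all(spec$voxelSize > 0),
            spec$nDroplets >= 0, spec$radiusMean > 0, spec$radiusSd >= 0,
            spec$blurSigma >= 0, spec$noiseSd >= 0,
            all(spec$adversarialComponents >= 1))
  class(spec) <- "dropletSpec"
  spec
}

# separable Gaussian blur of a 3D array (reflected edges)
.gaussBlur3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- ceiling(3 * sigma)
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  for (axis in 1:3) {
    n <- dim(a)[axis]
    out <- array(0, dim(a))
    for (k in -r:r) {
      idx <- seq_len(n) + k
      idx[idx < 1] <- 1 - idx[idx < 1]
      idx[idx > n] <- 2 * n + 1 - idx[idx > n]
      sl <- switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                   a[, , idx, drop = FALSE])
      out <- out + w[k + r + 1] * sl
    }
    a <- out
  }
  a
}

# compact connected block of exactly n voxels: raster fill of a cube
.compactBlock <- function(n) {
  side <- ceiling(n^(1 / 3))
  g <- expand.grid(i = seq_len(side), j = seq_len(side), k = seq_len(side))
  g <- g[order(g$k, g$j, g$i), ]
  as.matrix(g[seq_len(n), , drop = FALSE])
}

#' Generate a synthetic droplet probability stack with ground truth
#'
#' @param spec A \code{\link{dropletSpec}}.
#' @return A list with \code{stack} (3D array of probabilities in [0, 1]),
#'   \code{truth} (data.frame: droplet_id, centre indices, radius, voxels =
#'   exact digital-ball lattice count) and \code{adversarialVoxels} (integer
#'   vector of planted component sizes, possibly empty).
#' @export
generateDropletStack <- function(spec) {
  stopifnot(inherits(spec, "dropletSpec"))
  withr::with_seed(spec$seed, .generateDroplets(spec))
}

.generateDroplets <- function(spec) {
  dm <- spec$stackShape
  stack <- array(0, dm)
  n <- spec$nDroplets
  radii <- if (n) pmax(2, rnorm(n, spec$radiusMean, spec$radiusSd)) else numeric(0)
  ctr <- matrix(0L, n, 3)
  pad <- ceiling(3 * spec$blurSigma)
  maxTries <- 5000L
  for (i in seq_len(n)) {
    ri <- radii[i]
    m <- ceiling(ri) + 1L
    if (any(dm - 2 * m < 1))
      stop("droplet would leave the stack: radius too large for stackShape",
           call. = FALSE)
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      p <- vapply(1:3, function(a) {
        lo <- as.integer(m) + 1L
        hi <- as.integer(dm[a] - m)
        lo + sample.int(hi - lo + 1L, 1L) - 1L
      }, integer(1))
      if (i > 1) {
        j <- seq_len(i - 1L)
        dd <- sqrt(rowSums((ctr[j, , drop = FALSE] -
                              matrix(p, i - 1L, 3, byrow = TRUE))^2))
        if (any(dd < radii[j] + ri + 2 * pad + 2)) next
      }
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf("droplet placement failed after %d retries (droplet %d of %d overlaps); reduce nDroplets or radius",
                   maxTries, i, n), call. = FALSE)
    ctr[i, ] <- p
  }
  voxels <- integer(n)
  for (i in seq_len(n)) {
    off <- ballOffsets(radii[i])
    voxels[i] <- nrow(off)
    idx <- sweep(off, 2, ctr[i, ], "+")
    stack[idx] <- 1
  }
  stack <- .gaussBlur3d(stack, spec$blurSigma)
  mx <- max(stack)
  if (mx > 0) stack <- stack / mx        # rescale to peak 1
  if (spec$noiseSd > 0)
    stack <- stack + array(rnorm(length(stack), 0, spec$noiseSd), dm)

  # adversarial blocks: planted after blur/noise so voxel counts are exact
  adv <- spec$adversarialComponents
  if (length(adv)) {
    sep <- 8L                             # > 2 * (opening radius 2 + 1)
    pos <- 2L
    for (a in seq_along(adv)) {
      blk <- .compactBlock(adv[a])
      side <- max(blk)
      if (pos + side > dm[1] - 1 || side + 3 > min(dm[2], dm[3]))
        stop("adversarial components do not fit in the stack", call. = FALSE)
      idx <- cbind(blk[, 1] + pos, blk[, 2] + 2L, blk[, 3] + 2L)
      # refuse to merge with droplets
      near <- any(vapply(seq_len(n), function(i)
        sqrt(min(rowSums(sweep(idx, 2, ctr[i, ], "-")^2))) <
          radii[i] + pad + sep, logical(1)))
      if (isTRUE(near))
        stop("adversarial component would touch a droplet; use a larger stack",
             call. = FALSE)
      # clear a guard shell so the block stays an isolated component
      g1 <- max(1, pos - 2):min(dm[1], pos + side + 2)
      g2 <- max(1, 1):min(dm[2], side + 4)
      g3 <- max(1, 1):min(dm[3], side + 4)
      stack[g1, g2, g3] <- 0
      stack[idx] <- 1
      pos <- pos + side + sep
    }
  }
  stack <- pmin(pmax(stack, 0), 1)
  truth <- data.frame(droplet_id = seq_len(n),
                      centre_1 = ctr[, 1], centre_2 = ctr[, 2],
                      centre_3 = ctr[, 3], radius = radii, voxels = voxels)
  list(stack = stack, truth = truth,
       adversarialVoxels = adv)
}
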