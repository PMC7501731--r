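# Independent oracles used throughout the suite. These deliberately share
# no code with the package internals: plain-R brute force, direct set
# definitions and exhaustive enumeration.

# reflect an out-of-range index into 1..n ('symmetric' boundary)
reflectIdx <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# brute-force disk median filter with reflected edges
bruteMedian <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  offs <- subset(expand.grid(di = -r:r, dj = -r:r), di^2 + dj^2 <= r^2)
  for (i in seq_len(nr))
    for (j in seq_len(nc)) {
      v <- mapply(function(di, dj)
        img[reflectIdx(i + di, nr), reflectIdx(j + dj, nc)],
        offs$di, offs$dj)
      out[i, j] <- median(v)
    }
  out
}

# exhaustive Otsu: scan every midpoint between consecutive sorted unique
# values, minimising within-class variance
exhaustiveOtsu <- function(x) {
  x <- as.vector(x)
  u <- sort(unique(x))
  cand <- (u[-1] + u[-length(u)]) / 2
  wcv <- vapply(cand, function(t) {
    lo <- x < t
    s <- 0
    if (any(lo)) s <- s + sum((x[lo] - mean(x[lo]))^2)
    if (any(!lo)) s <- s + sum((x[!lo] - mean(x[!lo]))^2)
    s
  }, numeric(1))
  cand[which.min(wcv)]
}

# independent flood-fill 3D labelling (breadth-first over whole frontiers,
# plain R; coordinates kept as (i, j, k) triples)
floodLabel3 <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  if (connectivity == 18) off <- off[rowSums(abs(off)) <= 2, , drop = FALSE]
  lab <- array(0L, dm)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start]) next
    nxt <- nxt + 1L
    lab[start] <- nxt
    rem <- start - 1L
    frontier <- cbind(rem %% dm[1] + 1L,
                      (rem %/% dm[1]) %% dm[2] + 1L,
                      rem %/% (dm[1] * dm[2]) + 1L)
    while (nrow(frontier)) {
      nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(o)
        sweep(frontier, 2, off[o, ], "+")))
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
        nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dm[1] + (nb[, 3] - 1L) * dm[1] * dm[2]
      keep <- !duplicated(lin)
      nb <- nb[keep, , drop = FALSE]
      lin <- lin[keep]
      grow <- mask[lin] & lab[lin] == 0L
      lab[lin[grow]] <- nxt
      frontier <- nb[grow, , drop = FALSE]
    }
  }
  lab
}

# digital Euclidean ball offsets by direct enumeration
oracleBallOffsets <- function(r) {
  g <- as.matrix(expand.grid(di = -ceiling(r):ceiling(r),
                             dj = -ceiling(r):ceiling(r),
                             dk = -ceiling(r):ceiling(r)))
  g[g[, 1]^2 + g[, 2]^2 + g[, 3]^2 <= r^2, , drop = FALSE]
}

# erosion / dilation by the set definition, plain R
oracleErode <- function(mask, off) {
  dm <- dim(mask)
  out <- array(FALSE, dm)
  fg <- which(mask, arr.ind = TRUE)
  for (v in seq_len(nrow(fg))) {
    p <- fg[v, ]
    nb <- sweep(off, 2, p, "+")
    inside <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
      nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
    out[p[1], p[2], p[3]] <- all(inside) && all(mask[nb[inside, , drop = FALSE]])
  }
  out
}

oracleDilate <- function(mask, off) {
  dm <- dim(mask)
  out <- array(FALSE, dm)
  fg <- which(mask, arr.ind = TRUE)
  for (v in seq_len(nrow(fg))) {
    nb <- sweep(off, 2, fg[v, ], "+")
    inside <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
      nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
    out[nb[inside, , drop = FALSE]] <- TRUE
  }
  out
}

# full droplet reference pipeline from the oracles above
oracleDropletPipeline <- function(stack, threshold = 0.5, min_voxels = 27,
                                  radius = 2, connectivity = 26) {
  b <- stack >= threshold
  dim(b) <- dim(stack)
  lab <- floodLabel3(b, connectivity)
  if (max(lab) > 0) {
    sz <- tabulate(lab[lab > 0], nbins = max(lab))
    b[lab %in% which(sz < min_voxels)] <- FALSE
  }
  if (radius > 0) {
    off <- oracleBallOffsets(radius)
    b <- oracleDilate(oracleErode(b, off), off)
  }
  b
}

# lattice-point count of a digital disk / ball
latticeDiskCount <- function(r) {
  g <- expand.grid(x = -ceiling(r):ceiling(r), y = -ceiling(r):ceiling(r))
  sum(g$x^2 + g$y^2 <= r^2)
}
latticeBallCount <- function(r) nrow(oracleBallOffsets(r))

# shoelace area of an (x, y) polygon matrix
shoelaceArea <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# a 3D array holding one centred digital ball of the given radius
ballArray <- function(r, margin = 4) {
  side <- 2 * ceiling(r) + 2 * margin + 1
  a <- array(FALSE, c(side, side, side))
  ctr <- rep(ceiling(r) + margin + 1, 3)
  a[sweep(oracleBallOffsets(r), 2, ctr, "+")] <- TRUE
  a
}

# small image with intensity disks on constant background (noise-free)
diskImage <- function(nr, nc, centers, radius, fg = 200, bg = 10,
                      channel = "F4/80", pixelSize = 1) {
  m <- matrix(bg, nr, nc)
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(nr) - centers[i, 1])^2,
                (seq_len(nc) - centers[i, 2])^2, "+")
    m[d2 <= radius^2] <- fg
  }
  chs <- list(m)
  names(chs) <- channel
  MultiplexImage(chs, pixelSize = pixelSize, imageId = "fixture")
}

# match detections to truth cells by nearest centroid
matchToTruth <- function(det, truth) {
  tb <- featureTable(det)
  vapply(seq_len(nrow(tb)), function(i) {
    d2 <- (truth$centroid_row - tb$centroid_row[i])^2 +
      (truth$centroid_col - tb$centroid_col[i])^2
    which.min(d2)
  }, integer(1))
}
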