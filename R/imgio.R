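# I/O for every artifact the pipeline touches: multi-channel TIFFs, label
# images, 3D probability stacks, GeoJSON annotations, CSV tables and the
# plain-text key=value configuration format.
#
# The TIFF writer stores channel names in a plain-text sidecar
# ("<path>.channels"); the reader uses the sidecar when present and
# otherwise falls back to caller-supplied positional names.

.sidecarPath <- function(path) paste0(path, ".channels")

#' Write a MultiplexImage as a multi-page TIFF
#'
#' One grayscale page per channel. Integer-valued channels with a maximum
#' below 2^16 are stored as 16-bit (lossless round-trip); anything else is
#' stored as 32-bit float with a recorded scale. Channel names and the pixel
#' size go to a plain-text sidecar next to the file.
#'
#' @param image A \linkS4class{MultiplexImage}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeMultichannelTiff <- function(image, path) {
  stopifnot(is(image, "MultiplexImage"))
  ch <- image@channels
  allint <- all(vapply(ch, function(m)
    max(m) < 65536 && all(m == round(m)), logical(1)))
  if (allint) {
    pages <- lapply(ch, function(m) m / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    scale <- 65535
    fmt <- "uint16"
  } else {
    scale <- max(1, vapply(ch, max, numeric(1)))
    pages <- lapply(ch, function(m) m / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    fmt <- "float32"
  }
  side <- c(sprintf("format=%s", fmt), sprintf("scale=%.17g", scale),
            sprintf("pixel_size=%.17g", image@pixelSize),
            sprintf("image_id=%s", image@imageId),
            sprintf("channel_%d=%s", seq_along(ch), names(ch)))
  writeLines(side, .sidecarPath(path))
  invisible(path)
}

#' Read a multi-channel TIFF into a MultiplexImage
#'
#' Channel names are taken from the sidecar written by
#' \code{\link{writeMultichannelTiff}} when present, else from
#' \code{channelNames} in page order. Requested names resolve
#' case-insensitively through the alias rule (punctuation ignored, so
#' \code{"F4-80"} matches \code{"F4/80"}).
#'
#' @param path TIFF file path.
#' @param channelNames Positional channel names used when no sidecar exists.
#' @param pixelSize Micrometres per pixel; overrides the sidecar value when
#'   given.
#' @return A \linkS4class{MultiplexImage}.
#' @export
readMultichannelTiff <- function(path, channelNames = NULL, pixelSize = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # integer pages arrive normalised to [0, 1]; undo the bit-depth scaling
  # (float pages, bits.per.sample 32, are stored as written)
  pages <- lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample")
    if (!is.null(bits) && bits <= 16) round(p * (2^bits - 1)) else p
  })
  scale <- 1
  px <- 1
  id <- basename(path)
  nm <- NULL
  sc <- .sidecarPath(path)
  if (file.exists(sc)) {
    kv <- .parseKeyValues(readLines(sc))
    fmt <- kv[["format"]]
    if (identical(fmt, "float32")) scale <- as.numeric(kv[["scale"]])
    if (!is.null(kv[["pixel_size"]])) px <- as.numeric(kv[["pixel_size"]])
    if (!is.null(kv[["image_id"]])) id <- kv[["image_id"]]
    ord <- grep("^channel_", names(kv))
    if (length(ord))
      nm <- unlist(kv[ord])[order(as.integer(sub("channel_", "", names(kv)[ord])))]
  }
  if (is.null(nm)) {
    if (is.null(channelNames))
      stop("no channel metadata found; supply channelNames", call. = FALSE)
    if (length(channelNames) > length(pages))
      stop(sprintf("file has %d pages but %d channel names were given",
                   length(pages), length(channelNames)), call. = FALSE)
    pages <- pages[seq_along(channelNames)]
    nm <- channelNames
  }
  channels <- lapply(pages, function(p) {
    m <- as.matrix(p[, , drop = TRUE])
    attributes(m)[setdiff(names(attributes(m)), "dim")] <- NULL
    m * scale
  })
  names(channels) <- nm
  if (!is.null(pixelSize)) px <- pixelSize
  img <- MultiplexImage(channels, pixelSize = px, imageId = id)
  if (!is.null(channelNames))
    for (cn in channelNames) getChannel(img, cn)   # fail early, names listed
  img
}

#' Write / read an integer label image as TIFF
#'
#' 16-bit for label values below 2^16, 32-bit float otherwise; round-trips
#' are exact.
#'
#' @param labels Integer matrix (2D) of labels (0 = background).
#' @param path File path.
#' @return \code{writeLabelTiff}: \code{path} invisibly;
#'   \code{readLabelTiff}: the integer label matrix.
#' @export
writeLabelTiff <- function(labels, path) {
  mx <- max(labels, 1)
  if (mx < 65536) {
    tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(labels / mx, path, bits.per.sample = 32L)
    writeLines(sprintf("scale=%.17g", mx), .sidecarPath(path))
  }
  invisible(path)
}

#' @rdname writeLabelTiff
#' @export
readLabelTiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- tiff::readTIFF(path, info = TRUE)
  bits <- attr(m, "bits.per.sample")
  m <- as.matrix(m[, , drop = TRUE])
  if (!is.null(bits) && bits <= 16) m <- round(m * (2^bits - 1))
  sc <- .sidecarPath(path)
  if (file.exists(sc)) {
    kv <- .parseKeyValues(readLines(sc))
    if (!is.null(kv[["scale"]])) m <- round(m * as.numeric(kv[["scale"]]))
  }
  storage.mode(m) <- "integer"
  attributes(m)[setdiff(names(attributes(m)), "dim")] <- NULL
  m
}

#' Write / read a 3D float stack as a multi-page TIFF
#'
#' One 32-bit float page per slice along the third array dimension. Values
#' must lie in [0, 1] (probability maps).
#'
#' @param stack 3D numeric array with values in [0, 1].
#' @param path File path.
#' @return \code{writeStackTiff}: \code{path} invisibly;
#'   \code{readStackTiff}: the 3D array.
#' @export
writeStackTiff <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  if (min(stack) < 0 || max(stack) > 1)
    stop("stack values must lie in [0, 1]", call. = FALSE)
  pages <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname writeStackTiff
#' @export
readStackTiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) as.matrix(p[, , drop = TRUE]))
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

# ---- polygon tracing ------------------------------------------------------

# Trace the outer boundary of a binary mask along pixel-square edges
# ("crack" boundary). Returns an n x 2 matrix of (x, y) corner coordinates,
# 0-based, y increasing downward; the enclosed area equals the pixel count
# exactly for hole-free masks. Collinear runs are merged.
.traceBoundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask, arr.ind = TRUE)
  if (!nrow(fg)) return(NULL)
  key <- function(r, c) (r - 1L) * (nc + 1L) + c     # corner id, corners 1..nr+1 x 1..nc+1
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  bgUp    <- !pad[cbind(fg[, 1], fg[, 2] + 1L)]
  bgDown  <- !pad[cbind(fg[, 1] + 2L, fg[, 2] + 1L)]
  bgLeft  <- !pad[cbind(fg[, 1] + 1L, fg[, 2])]
  bgRight <- !pad[cbind(fg[, 1] + 1L, fg[, 2] + 2L)]
  # directed edges (from-corner, to-corner, direction code 1=+x 2=+y 3=-x 4=-y)
  e <- rbind(
    if (any(bgUp)) cbind(key(fg[bgUp, 1], fg[bgUp, 2]),
                         key(fg[bgUp, 1], fg[bgUp, 2] + 1L), 1L),
    if (any(bgRight)) cbind(key(fg[bgRight, 1], fg[bgRight, 2] + 1L),
                            key(fg[bgRight, 1] + 1L, fg[bgRight, 2] + 1L), 2L),
    if (any(bgDown)) cbind(key(fg[bgDown, 1] + 1L, fg[bgDown, 2] + 1L),
                           key(fg[bgDown, 1] + 1L, fg[bgDown, 2]), 3L),
    if (any(bgLeft)) cbind(key(fg[bgLeft, 1] + 1L, fg[bgLeft, 2]),
                           key(fg[bgLeft, 1], fg[bgLeft, 2]), 4L))
  used <- rep(FALSE, nrow(e))
  ord <- order(e[, 1])
  e <- e[ord, , drop = FALSE]
  starts <- e[, 1]
  loops <- list()
  # right-turn preference relative to incoming direction keeps the walk on
  # one tight boundary when two loops share a corner (8-connected pinch)
  turnPref <- function(dir) (c(dir + 1L, dir, dir - 1L, dir + 2L) - 1L) %% 4L + 1L
  for (s in seq_len(nrow(e))) {
    if (used[s]) next
    path <- integer(0)
    cur <- s
    repeat {
      used[cur] <- TRUE
      path <- c(path, cur)
      nxt <- which(starts == e[cur, 2] & !used)
      if (!length(nxt)) break
      if (length(nxt) > 1) {
        pref <- turnPref(e[cur, 3])
        nxt <- nxt[order(match(e[nxt, 3], pref))][1]
      }
      cur <- nxt[1]
    }
    loops[[length(loops) + 1L]] <- path
  }
  corners <- function(k) cbind(x = (k - 1L) %% (nc + 1L),
                               y = (k - 1L) %/% (nc + 1L))
  polys <- lapply(loops, function(p) corners(e[p, 1]))
  areas <- vapply(polys, function(v) abs(.shoelace(v)), numeric(1))
  poly <- polys[[which.max(areas)]]
  # merge collinear runs
  n <- nrow(poly)
  if (n > 2) {
    d <- diff(rbind(poly, poly[1, ]))
    keep <- c(TRUE, rowSums(abs(diff(d))) != 0)
    poly <- poly[keep, , drop = FALSE]
  }
  poly
}

.shoelace <- function(v) {
  n <- nrow(v)
  if (n < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# ---- GeoJSON annotations --------------------------------------------------

#' Export detections as a GeoJSON FeatureCollection
#'
#' One polygon feature per detection: the outer crack boundary of the cell
#' mask (holes are filled upstream), in (x = column, y = row) coordinates
#' with y increasing downward, 0-based, the convention of common
#' digital-pathology viewers. Class, centroid and measurements travel as
#' feature properties. Detections with an empty mask are skipped with a
#' warning.
#'
#' @param detections A \linkS4class{CellDetections}.
#' @param path Optional output file; when NULL the GeoJSON list is returned.
#' @param stamp Optional named character vector added as top-level properties
#'   (e.g. config hash and seed).
#' @return The GeoJSON structure (list), invisibly when written to file.
#' @export
exportAnnotations <- function(detections, path = NULL, stamp = NULL) {
  stopifnot(is(detections, "CellDetections"))
  tb <- featureTable(detections)
  lab <- labelImage(detections)
  feats <- list()
  for (i in seq_len(nrow(tb))) {
    id <- tb$cell_id[i]
    px <- which(lab == id, arr.ind = TRUE)
    if (!nrow(px)) {
      warning(sprintf("detection %d has an empty mask; skipped", id))
      next
    }
    r0 <- min(px[, 1]); c0 <- min(px[, 2])
    sub <- matrix(FALSE, max(px[, 1]) - r0 + 1L, max(px[, 2]) - c0 + 1L)
    sub[cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L)] <- TRUE
    poly <- .traceBoundary(sub)
    poly[, "x"] <- poly[, "x"] + (c0 - 1L)
    poly[, "y"] <- poly[, "y"] + (r0 - 1L)
    ring <- rbind(poly, poly[1, , drop = FALSE])
    props <- as.list(tb[i, setdiff(names(tb), "cell_id")])
    props$cell_id <- id
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(unname(ring))),
      properties = props)
  }
  gj <- list(type = "FeatureCollection",
             image_id = imageId(detections),
             pixel_size = pixelSize(detections),
             features = feats)
  if (!is.null(stamp)) gj$properties <- as.list(stamp)
  if (!is.null(path)) {
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
    return(invisible(gj))
  }
  gj
}

#' Import a GeoJSON FeatureCollection written by exportAnnotations
#'
#' @param path GeoJSON file.
#' @return A list with \code{table} (data.frame of feature properties, one
#'   row per feature), \code{polygons} (list of (x, y) vertex matrices),
#'   \code{image_id} and \code{pixel_size}.
#' @export
importAnnotations <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection", call. = FALSE)
  feats <- gj$features
  polys <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    colnames(m) <- c("x", "y")
    m
  })
  tb <- do.call(rbind, lapply(feats, function(f)
    as.data.frame(f$properties, stringsAsFactors = FALSE)))
  list(table = tb, polygons = polys,
       image_id = gj$image_id, pixel_size = gj$pixel_size)
}

# ---- CSV tables -----------------------------------------------------------

#' Write / read a CSV result table
#'
#' Tables may carry leading '#' comment lines (run stamps); the reader skips
#' them, so written values round-trip exactly as read.
#'
#' @param df data.frame.
#' @param path File path.
#' @param stamp Optional character vector written as leading '#' comments.
#' @return \code{readTableCsv}: the data.frame.
#' @export
writeTableCsv <- function(df, path, stamp = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(stamp)) writeLines(paste0("# ", stamp), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTableCsv
#' @export
readTableCsv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# ---- plain-text key=value configuration ----------------------------------

.parseKeyValues <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  eq <- regexpr("=", lines, fixed = TRUE)
  keys <- trimws(substr(lines, 1, eq - 1))
  vals <- trimws(substr(lines, eq + 1, nchar(lines)))
  setNames(as.list(vals), keys)
}

.flattenConfig <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    v <- x[[nm]]
    if (is.list(v) && !is.null(names(v))) {
      out <- c(out, .flattenConfig(v, key))
    } else {
      out[[key]] <- v
    }
  }
  out
}

#' Write / read a plain-text key=value configuration
#'
#' Nested lists flatten to dotted keys; vectors serialize comma-separated.
#' \code{readConfig} re-nests dotted keys and converts values back to
#' numeric/logical where unambiguous, so serialize -> parse -> serialize is
#' the identity for configs of plain types.
#'
#' @param config Named (possibly nested) list of scalars/vectors.
#' @param path File path.
#' @return \code{readConfig}: the nested list.
#' @export
writeConfig <- function(config, path) {
  flat <- .flattenConfig(config)
  fmtv <- function(v) {
    if (is.numeric(v)) paste(vapply(v, function(e) format(e, digits = 17),
                                    character(1)), collapse = ",")
    else paste(as.character(v), collapse = ",")
  }
  writeLines(sprintf("%s=%s", names(flat),
                     vapply(flat, fmtv, character(1))), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  kv <- .parseKeyValues(readLines(path))
  conv <- function(s) {
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    if (length(parts) == 0) return("")
    if (all(parts %in% c("TRUE", "FALSE"))) return(as.logical(parts))
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) return(num)
    if (length(parts) == 1) s else parts
  }
  out <- list()
  for (k in names(kv)) {
    keys <- strsplit(k, ".", fixed = TRUE)[[1]]
    out <- .assignNested(out, keys, conv(kv[[k]]))
  }
  out
}

.assignNested <- function(lst, keys, value) {
  if (length(keys) == 1) {
    lst[[keys]] <- value
  } else {
    if (is.null(lst[[keys[1]]])) lst[[keys[1]]] <- list()
    lst[[keys[1]]] <- .assignNested(lst[[keys[1]]], keys[-1], value)
  }
  lst
}
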