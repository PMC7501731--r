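# End-to-end orchestration: simulate (or load) -> detect -> classify ->
# zones -> quantify, with one global seed, a config echo, and every output
# stamped with the config hash + seed. Re-running with an identical config
# reproduces identical outputs.

#' Default pipeline configuration
#'
#' Returns the full nested configuration understood by
#' \code{\link{runPipeline}}. Override entries by name; unknown keys raise
#' an error inside the stage constructors. The \code{simulate} block holds
#' \code{\link{tissueSpec}} arguments and is only used when
#' \code{input} is NULL.
#'
#' @param ... Named overrides merged (recursively) into the defaults.
#' @return Nested configuration list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    input = NULL,                 # path to a multi-channel TIFF; NULL = simulate
    channels = canonicalChannels(),
    out_dir = NULL,
    vessel_source = "external-mask",   # "external-mask", "auto" or "none"
    vessel_mask = NULL,                # label/binary TIFF path or matrix
    simulate = list(),                 # tissueSpec() overrides
    detection = list(),                # detectionParams() overrides
    classification = list(),           # classParams() overrides
    zoning = list()                    # zoneParams() overrides
  )
  .mergeConfig(cfg, list(...))
}

.mergeConfig <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Run the full quantification pipeline
#'
#' Executes detect -> classify -> zones -> quantify on a loaded or
#' simulated image, applies vessel exclusion per \code{vessel_source}, and
#' (when \code{out_dir} is set) writes the config echo, detections
#' (GeoJSON + label TIFF), feature table, zone map and composition table,
#' each stamped with the config hash and seed.
#'
#' @param config A \code{\link{pipelineConfig}} list or the path of a
#'   key=value config file (see \code{\link{readConfig}}).
#' @return A list with \code{composition} (data.frame),
#'   \code{detections} (\linkS4class{CellDetections}), \code{zonemap}
#'   (\linkS4class{ZoneMap}), \code{truth} (simulation only) and
#'   \code{config_hash}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- .mergeConfig(pipelineConfig(),
                                                   readConfig(config))
  stopifnot(is.list(config))
  seed <- as.integer(config$seed)

  truth <- NULL
  vesselMask <- NULL
  if (is.null(config$input)) {
    spec <- do.call(tissueSpec, c(config$simulate,
                                  if (is.null(config$simulate$seed))
                                    list(seed = seed)))
    message(sprintf("[pipeline] simulating tissue image (seed %d)", spec$seed))
    sim <- generateTissueImage(spec)
    image <- sim$image
    truth <- sim$truth
    if (identical(config$vessel_source, "external-mask") &&
        is.null(config$vessel_mask))
      config$vessel_mask <- sim$vesselMask
  } else {
    if (!file.exists(config$input))
      stop("config field 'input' names a missing file: ", config$input,
           call. = FALSE)
    image <- readMultichannelTiff(config$input, config$channels)
  }

  detPar <- do.call(detectionParams, config$detection)
  clsPar <- do.call(classParams, config$classification)
  zonPar <- do.call(zoneParams, config$zoning)

  message("[pipeline] detection")
  det <- detectMacrophages(image, detPar)
  message(sprintf("[pipeline] %d detections; feature extraction + classification",
                  nDetections(det)))
  det <- classifyCells(extractFeatures(det, image, clsPar), clsPar)

  message("[pipeline] zoning")
  zm <- segmentDesminZones(image, zonPar)
  vs <- config$vessel_source
  if (identical(vs, "external-mask")) {
    if (is.null(config$vessel_mask))
      stop("vessel_source is 'external-mask' but config field 'vessel_mask' is missing",
           call. = FALSE)
    vm <- config$vessel_mask
    if (is.character(vm)) vm <- readLabelTiff(vm) > 0
    vesselMask <- vm
  } else if (identical(vs, "auto")) {
    vesselMask <- suppressMessages(autoVesselMask(image, zonPar))
  } else if (!identical(vs, "none")) {
    stop("config field 'vessel_source' must be external-mask, auto or none",
         call. = FALSE)
  }
  if (!is.null(vesselMask)) zm <- applyVesselExclusion(zm, vesselMask)

  det <- assignZones(det, zm)
  comp <- quantifyComposition(det)

  hash <- NA_character_
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    cfgPath <- file.path(config$out_dir, "config.txt")
    writeConfig(.serializableConfig(config), cfgPath)
    hash <- unname(tools::md5sum(cfgPath))
    stamp <- sprintf("config_hash=%s seed=%d", hash, seed)
    writeTableCsv(featureTable(det),
                  file.path(config$out_dir, "features.csv"), stamp)
    writeTableCsv(comp, file.path(config$out_dir, "composition.csv"), stamp)
    writeLabelTiff(labelImage(det), file.path(config$out_dir, "labels.tiff"))
    writeLabelTiff(zoneLabels(zm), file.path(config$out_dir, "zonemap.tiff"))
    exportAnnotations(det, file.path(config$out_dir, "detections.geojson"),
                      stamp = c(config_hash = hash, seed = seed))
    writeLines(c(stamp, sprintf("n_detections=%d", nDetections(det))),
               file.path(config$out_dir, "run_info.txt"))
  }
  list(composition = comp, detections = det, zonemap = zm, truth = truth,
       config_hash = hash)
}

# strip non-serializable entries (matrices, NULLs) before the config echo
.serializableConfig <- function(config) {
  keep <- function(x) is.numeric(x) || is.character(x) || is.logical(x)
  walk <- function(x) {
    out <- list()
    for (nm in names(x)) {
      v <- x[[nm]]
      if (is.list(v)) {
        w <- walk(v)
        if (length(w)) out[[nm]] <- w
      } else if (keep(v) && !is.matrix(v)) out[[nm]] <- v
    }
    out
  }
  walk(config)
}

#' Write droplet pipeline outputs
#'
#' Writes the label volume (multi-page TIFF), per-component CSV and a JSON
#' summary of a \linkS4class{DropletResult}.
#'
#' @param result A \linkS4class{DropletResult}.
#' @param dir Output directory (created if needed).
#' @param stamp Optional stamp string for the CSV/JSON outputs.
#' @return \code{dir}, invisibly.
#' @export
writeDropletResult <- function(result, dir, stamp = NULL) {
  stopifnot(is(result, "DropletResult"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lab <- result@labels
  if (max(lab, 1) < 65536) {
    pages <- lapply(seq_len(dim(lab)[3]), function(k) lab[, , k] / 65535)
    tiff::writeTIFF(pages, file.path(dir, "labels.tiff"),
                    bits.per.sample = 16L)
  }
  writeTableCsv(componentVolumes(result),
                file.path(dir, "components.csv"), stamp)
  jsonlite::write_json(
    list(n_components = length(result@componentVoxels),
         total_volume_voxels = sum(result@componentVoxels),
         total_volume_um3 = totalVolume(result, "um3"),
         voxel_size_nm = result@voxelSize,
         stamp = stamp),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
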