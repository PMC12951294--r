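#' Read and write pressure images
#'
#' Images are stored as single-channel 32-bit float TIFF with a JSON
#' sidecar (`<path>.json`) holding the pixel spacing, the affine scale and
#' offset used to map intensities into the TIFF's \[0, 1\] range (so signed
#' reconstructions survive the round trip), and provenance metadata.
#'
#' @param img a \linkS4class{PressureImage}.
#' @param path output TIFF path.
#' @param meta optional named list merged into the sidecar.
#' @return `writePressureImage` returns `path` invisibly;
#'   `readPressureImage` returns a \linkS4class{PressureImage}
#' @export
writePressureImage <- function(img, path, meta = list()) {
  p <- pixels(img)
  offset <- min(p)
  scale <- max(max(p) - offset, 1e-12)
  tiff::writeTIFF((p - offset) / scale, path, bits.per.sample = 32L,
                  reduce = TRUE)
  side <- c(list(spacing_mm = spacing(img), origin_mm = img@origin,
                 scale = scale, offset = offset), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writePressureImage
#' @export
readPressureImage <- function(path) {
  p <- tiff::readTIFF(path)
  if (length(dim(p)) == 3L) p <- p[, , 1]
  sidecar <- paste0(path, ".json")
  spacingMm <- 0.1; origin <- c(0, 0); scale <- 1; offset <- 0
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$spacing_mm)) spacingMm <- side$spacing_mm
    if (!is.null(side$origin_mm)) origin <- side$origin_mm
    if (!is.null(side$scale)) scale <- side$scale
    if (!is.null(side$offset)) offset <- side$offset
  }
  PressureImage(p * scale + offset, spacing = spacingMm, origin = origin)
}

#' Read and write sinograms
#'
#' Sinograms are stored as a plain tab-separated trace matrix (one row per
#' active detector) next to a JSON sidecar with the acquisition metadata
#' (dt, geometry, detector mask).
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param path output `.tsv` path.
#' @return `writeSinogram` returns `path` invisibly; `readSinogram` a
#'   \linkS4class{Sinogram}
#' @export
writeSinogram <- function(sino, path) {
  utils::write.table(traces(sino), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  g <- geometry(sino)
  side <- list(dt_us = sino@dt,
               geometry = list(radius = g@radius, nElements = g@nElements,
                               coverage = g@coverage,
                               startAngle = g@startAngle,
                               speedOfSound = g@speedOfSound,
                               samplingRate = g@samplingRate,
                               nSamples = g@nSamples),
               detectorMask = which(detectorMask(sino)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  tr <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(tr) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  gg <- side$geometry
  geom <- RingGeometry(radius = gg$radius, nElements = gg$nElements,
                       coverage = gg$coverage, startAngle = gg$startAngle,
                       speedOfSound = gg$speedOfSound,
                       samplingRate = gg$samplingRate,
                       nSamples = gg$nSamples)
  mask <- rep(FALSE, gg$nElements)
  mask[side$detectorMask] <- TRUE
  new("Sinogram", traces = tr, dt = side$dt_us, geometry = geom,
      detectorMask = mask)
}

#' Save and load network checkpoints
#'
#' The checkpoint is a native `.rds` of the network plus a JSON manifest
#' (`<path>.json`) recording the architecture, training step and seed.
#'
#' @param net a \linkS4class{NoiseNetwork}.
#' @param path output `.rds` path.
#' @param meta named list merged into the manifest (e.g. seed, schedule).
#' @return `saveCheckpoint` returns `path` invisibly; `loadCheckpoint` a
#'   \linkS4class{NoiseNetwork}
#' @export
saveCheckpoint <- function(net, path, meta = list()) {
  saveRDS(net, path)
  cfg <- net@config
  manifest <- c(list(step = as.integer(net@step),
                     baseChannels = cfg$baseChannels, blocks = cfg$blocks,
                     heads = cfg$heads, expansion = cfg$expansion,
                     timeDim = cfg$timeDim,
                     parameters = countParameters(net)), meta)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) readRDS(path)
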