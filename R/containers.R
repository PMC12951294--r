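#' Construct a PressureImage
#'
#' @param pixels numeric matrix (H x W) of intensities.
#' @param spacing pixel pitch in mm.
#' @param origin physical coordinate (mm) of the grid center.
#' @return a \linkS4class{PressureImage}
#' @examples
#' img <- PressureImage(matrix(0, 64, 64), spacing = 0.2)
#' dim(pixels(img))
#' @export
PressureImage <- function(pixels, spacing = 0.1, origin = c(0, 0)) {
  new("PressureImage", pixels = pixels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname PressureImage-class
#' @export
setMethod("pixels", "PressureImage", function(x) x@pixels)

#' @rdname PressureImage-class
#' @export
setMethod("spacing", "PressureImage", function(x) x@spacing)

#' @rdname PressureImage-class
#' @export
setMethod("dim", "PressureImage", function(x) dim(x@pixels))

setMethod("show", "PressureImage", function(object) {
  p <- object@pixels
  cat(sprintf("PressureImage: %d x %d px, %.4g mm/px (%.3g x %.3g mm)\n",
              nrow(p), ncol(p), object@spacing,
              nrow(p) * object@spacing, ncol(p) * object@spacing))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(p), max(p)))
})

#' Construct a RingGeometry
#'
#' Defaults describe the acquisition studied throughout the package: a full
#' 512-element ring of radius 40 mm, sampling at 62.5 MHz, speed of sound
#' 1500 m/s. `nSamples = NA` picks the smallest count whose time window
#' covers every arrival from a grid of the given extent (ring radius plus
#' half the image diagonal, plus margin).
#'
#' @param radius ring radius, mm.
#' @param nElements number of elements on the arc.
#' @param coverage angular coverage, radians, in (0, 2*pi].
#' @param startAngle angle of the first element, radians.
#' @param speedOfSound m/s.
#' @param samplingRate MHz.
#' @param nSamples samples per trace, or NA to derive from `imageExtent`.
#' @param imageExtent largest physical image width/height (mm) the geometry
#'   must cover when `nSamples` is NA.
#' @return a \linkS4class{RingGeometry}
#' @examples
#' geom <- RingGeometry(nElements = 128, imageExtent = 20)
#' geom
#' @export
RingGeometry <- function(radius = 40, nElements = 512L, coverage = 2 * pi,
                         startAngle = 0, speedOfSound = 1500,
                         samplingRate = 62.5, nSamples = NA,
                         imageExtent = 25.6) {
  if (is.na(nSamples)) {
    vmmus <- speedOfSound / 1000          # mm per microsecond
    rmax <- radius + imageExtent * sqrt(2) / 2
    nSamples <- ceiling(rmax / vmmus * samplingRate) + 8L
  }
  new("RingGeometry", radius = as.numeric(radius),
      nElements = as.integer(nElements), coverage = as.numeric(coverage),
      startAngle = as.numeric(startAngle),
      speedOfSound = as.numeric(speedOfSound),
      samplingRate = as.numeric(samplingRate),
      nSamples = as.integer(nSamples))
}

#' @rdname RingGeometry-class
#' @export
setMethod("nElements", "RingGeometry", function(x) x@nElements)

#' @rdname RingGeometry-class
#' @export
setMethod("samplingRate", "RingGeometry", function(x) x@samplingRate)

#' @rdname RingGeometry-class
#' @export
setMethod("speedOfSound", "RingGeometry", function(x) x@speedOfSound)

setMethod("show", "RingGeometry", function(object) {
  cat(sprintf(
    "RingGeometry: %d elements, radius %.3g mm, coverage %.4g rad\n",
    object@nElements, object@radius, object@coverage))
  cat(sprintf("  v = %g m/s, fs = %g MHz, %d samples (%.3g us window)\n",
              object@speedOfSound, object@samplingRate, object@nSamples,
              object@nSamples / object@samplingRate))
})

#' Construct a Sinogram
#'
#' Usually produced by [simulateSignals()] rather than called directly.
#'
#' @param traces nDet x nT matrix of pressure samples.
#' @param geometry the full-ring \linkS4class{RingGeometry}.
#' @param detectorMask logical over the full ring; defaults to all active.
#' @return a \linkS4class{Sinogram}
#' @export
Sinogram <- function(traces, geometry,
                     detectorMask = rep(TRUE, nElements(geometry))) {
  new("Sinogram", traces = traces, dt = 1 / geometry@samplingRate,
      geometry = geometry, detectorMask = detectorMask)
}

#' @rdname Sinogram-class
#' @export
setMethod("traces", "Sinogram", function(x) x@traces)

#' @rdname Sinogram-class
#' @export
setMethod("detectorMask", "Sinogram", function(x) x@detectorMask)

#' @rdname Sinogram-class
#' @export
setMethod("geometry", "Sinogram", function(x) x@geometry)

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d detectors x %d samples, dt = %.4g us\n",
              nrow(object@traces), ncol(object@traces), object@dt))
  cat(sprintf("  %d / %d ring elements active\n",
              sum(object@detectorMask), length(object@detectorMask)))
})

#' Construct a FilterSpec
#'
#' @param order Butterworth order (default 3).
#' @param band (low, high) cutoff frequencies in MHz (default 0.5--10).
#' @param derivativeWeight weight of the `t * dp/dt` ramp term (default 1).
#' @return a \linkS4class{FilterSpec}
#' @examples
#' FilterSpec()
#' @export
FilterSpec <- function(order = 3L, band = c(0.5, 10), derivativeWeight = 1) {
  new("FilterSpec", order = as.integer(order), band = as.numeric(band),
      derivativeWeight = as.numeric(derivativeWeight))
}

setMethod("show", "FilterSpec", function(object) {
  cat(sprintf(
    "FilterSpec: order-%d Butterworth band-pass %.3g-%.3g MHz (dweight %g)\n",
    object@order, object@band[1], object@band[2], object@derivativeWeight))
})

#' Construct a ReconGrid
#'
#' @param shape (H, W) in pixels; a single number gives a square grid.
#'   Default 500 x 500.
#' @param extent physical (width, height) in mm; a single number gives a
#'   square extent. The grid is centered on the ring center.
#' @return a \linkS4class{ReconGrid}
#' @examples
#' ReconGrid(500, 25)
#' @export
ReconGrid <- function(shape = 500L, extent = 25.6) {
  if (length(shape) == 1L) shape <- c(shape, shape)
  if (length(extent) == 1L) extent <- c(extent, extent)
  new("ReconGrid", shape = as.integer(shape), extent = as.numeric(extent))
}

setMethod("show", "ReconGrid", function(object) {
  cat(sprintf("ReconGrid: %d x %d px over %.3g x %.3g mm\n",
              object@shape[1], object@shape[2],
              object@extent[1], object@extent[2]))
})

# physical pixel-center coordinates (mm) of a grid, ring-centered.
# Returns a (H*W) x 2 matrix in column-major pixel order.
gridCoords <- function(H, W, spacingX, spacingY = spacingX) {
  x <- (rep(seq_len(W), each = H) - (W + 1) / 2) * spacingX
  y <- (rep(seq_len(H), times = W) - (H + 1) / 2) * spacingY
  cbind(x = x, y = y)
}
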