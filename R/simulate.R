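#' Detector positions on the ring
#'
#' Elements are spaced arc-uniformly over the coverage angle, the first one
#' at `startAngle`, so a full ring has pitch `2*pi / nElements` and a
#' partial arc of coverage Omega has pitch `Omega / nElements`.
#'
#' @param geom a \linkS4class{RingGeometry}.
#' @return nElements x 2 matrix of (x, y) coordinates in mm
#' @examples
#' detectorPositions(RingGeometry(nElements = 4L))
#' @export
detectorPositions <- function(geom) {
  ang <- geom@startAngle +
    geom@coverage * (seq_len(geom@nElements) - 1) / geom@nElements
  cbind(x = geom@radius * cos(ang), y = geom@radius * sin(ang))
}

#' Simulate ring-array photoacoustic signals
#'
#' Idealized point-detector, lossless, homogeneous-medium forward model: the
#' trace recorded at detector d is the time derivative of the circular mean
#' of the initial pressure over circles centered at d with radius `v * t`.
#' The circular mean is discretized by binning pixels into radial bins of
#' width `v * dt` (one bin per time sample, bin k centered at radius
#' `(k - 1/2) * v * dt`); the derivative is a central finite difference.
#' The model is exactly linear in the image.
#'
#' Physical detector bandwidth is deliberately not applied here; the
#' band-pass of the reconstruction filter partially represents it.
#'
#' @param image a \linkS4class{PressureImage}; must fit inside the ring.
#' @param geom a \linkS4class{RingGeometry}; its time window must cover all
#'   arrivals from the grid.
#' @return a \linkS4class{Sinogram} with all ring elements active
#' @examples
#' img <- generatePhantom(PhantomSpec("disks", seed = 2), 64, spacing = 0.2)
#' geom <- RingGeometry(nElements = 16L, imageExtent = 12.8)
#' sino <- simulateSignals(img, geom)
#' @export
simulateSignals <- function(image, geom) {
  p <- pixels(image)
  H <- nrow(p); W <- ncol(p); sp <- spacing(image)
  halfDiag <- sqrt((H * sp)^2 + (W * sp)^2) / 2
  if (halfDiag >= geom@radius)
    stop("image extends outside the detector ring")
  vmmus <- geom@speedOfSound / 1000
  dt <- 1 / geom@samplingRate
  dr <- vmmus * dt
  nt <- geom@nSamples
  if ((nt - 2) * dr < geom@radius + halfDiag)
    stop("time window too short: arrivals would be truncated")
  coords <- gridCoords(H, W, sp)
  px <- coords[, 1] + image@origin[1]
  py <- coords[, 2] + image@origin[2]
  det <- detectorPositions(geom)
  vals <- as.numeric(p)
  rk <- (seq_len(nt) - 0.5) * dr              # bin-center radii
  tr <- matrix(0, geom@nElements, nt)
  for (d in seq_len(geom@nElements)) {
    s <- .binByDistance(vals, px, py, det[d, 1], det[d, 2], dr, nt)
    g <- s * sp^2 / dr / (2 * pi * rk)        # circular mean
    tr[d, 2:(nt - 1)] <- (g[3:nt] - g[1:(nt - 2)]) / (2 * dt)
  }
  Sinogram(tr, geom)
}

#' Subsample a sinogram's detectors
#'
#' Creates the sparse-view and limited-view acquisitions studied in the
#' package. Sparse mode keeps every (nElements/n)-th element starting at
#' element 1; limited mode keeps the contiguous block of
#' `floor(nElements * Omega / coverage)` elements starting at the ring's
#' start angle. Trace rows are passed through unmodified.
#'
#' @param sino a full-view \linkS4class{Sinogram}.
#' @param mode "sparse" or "limited".
#' @param param for sparse, the retained element count n (a divisor of
#'   nElements); for limited, the retained arc Omega in radians.
#' @return a \linkS4class{Sinogram} with an updated detector mask
#' @examples
#' img <- generatePhantom(PhantomSpec("disks", seed = 2), 64, spacing = 0.2)
#' sino <- simulateSignals(img, RingGeometry(nElements = 64L,
#'                                           imageExtent = 12.8))
#' sub <- subsampleViews(sino, "sparse", 16)
#' sum(detectorMask(sub))
#' @export
subsampleViews <- function(sino, mode = c("sparse", "limited"), param) {
  mode <- match.arg(mode)
  geom <- geometry(sino)
  ne <- geom@nElements
  if (!all(detectorMask(sino)))
    stop("subsampleViews expects a full-view sinogram")
  if (mode == "sparse") {
    if (param < 1 || param > ne || ne %% param != 0)
      stop("sparse element count must divide the ring's element count")
    keep <- seq(1L, ne, by = ne %/% as.integer(param))
  } else {
    if (param <= 0 || param > geom@coverage + 1e-12)
      stop("limited-view arc must lie in (0, coverage]")
    keep <- seq_len(max(1L, floor(ne * param / geom@coverage)))
  }
  mask <- rep(FALSE, ne)
  mask[keep] <- TRUE
  new("Sinogram", traces = traces(sino)[keep, , drop = FALSE],
      dt = sino@dt, geometry = geom, detectorMask = mask)
}
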