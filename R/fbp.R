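# zero-phase Butterworth band-pass magnitude response, evaluated at
# frequencies f (MHz). Product of an order-n high-pass and order-n low-pass
# magnitude, so each band edge is a -3 dB point of its own factor.
butterworthResponse <- function(f, spec) {
  af <- abs(f)
  n2 <- 2 * spec@order
  hp <- ifelse(af == 0, 0, 1 / sqrt(1 + (spec@band[1] / pmax(af, 1e-300))^n2))
  lp <- 1 / sqrt(1 + (af / spec@band[2])^n2)
  hp * lp
}

#' Evaluate the FBP band-pass filter response
#'
#' @param spec a \linkS4class{FilterSpec}.
#' @param f frequencies in MHz.
#' @return numeric vector of magnitudes in \[0, 1\]
#' @examples
#' filterResponse(FilterSpec(), c(0.5, 2, 10))
#' @export
filterResponse <- function(spec, f) butterworthResponse(f, spec)

# FFT frequency grid (MHz) for n samples at period dt (us)
fftFreqs <- function(n, dt) {
  c(seq.int(0L, floor(n / 2)), seq.int(-ceiling(n / 2) + 1L, -1L)) / (n * dt)
}

#' Filtered back-projection term
#'
#' Computes, per trace, `b = 2 F^-1{W F p} - w_d * t * F^-1{j omega W F p}`
#' where W is the zero-phase Butterworth band-pass window, omega = 2 pi f,
#' t is the time from acquisition start in microseconds (frequencies in MHz,
#' consistent units), and `w_d` is the spec's `derivativeWeight` (1 by
#' default; 2 gives the universal back-projection weighting).
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param filt a \linkS4class{FilterSpec}.
#' @return matrix of the same shape as `traces(sino)`
#' @export
backprojectionTerm <- function(sino, filt = FilterSpec()) {
  tr <- traces(sino)
  nt <- ncol(tr)
  nyq <- 1 / (2 * sino@dt)
  if (filt@band[2] >= nyq)
    stop("filter band must lie below the Nyquist frequency ", nyq, " MHz")
  f <- fftFreqs(nt, sino@dt)
  W <- butterworthResponse(f, filt)
  jwW <- 1i * 2 * pi * f * W
  tt <- (seq_len(nt) - 1) * sino@dt
  b <- matrix(0, nrow(tr), nt)
  for (d in seq_len(nrow(tr))) {
    P <- stats::fft(tr[d, ])
    sm <- Re(stats::fft(W * P, inverse = TRUE)) / nt
    dv <- Re(stats::fft(jwW * P, inverse = TRUE)) / nt
    b[d, ] <- 2 * sm - filt@derivativeWeight * tt * dv
  }
  b
}

#' Filtered back-projection reconstruction
#'
#' Back-projects the filtered term over time-of-flight circles:
#' `p0(r_s) = sum_d b(r_d, |r_s - r_d| / v) / N_active`, with linear
#' interpolation in time and uniform weights over the *active* detectors
#' (limited-view acquisitions are not renormalized to the full ring, which
#' reproduces their characteristic intensity loss). The output keeps its
#' signed values; map to \[0, 255\] separately for dataset use.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param grid a \linkS4class{ReconGrid}, strictly inside the ring.
#' @param filt a \linkS4class{FilterSpec}.
#' @return a signed \linkS4class{PressureImage}
#' @examples
#' img <- generatePhantom(PhantomSpec("disks", seed = 2), 64, spacing = 0.2)
#' geom <- RingGeometry(nElements = 64L, imageExtent = 12.8)
#' rec <- fbpReconstruct(simulateSignals(img, geom), ReconGrid(64L, 12.8))
#' @export
fbpReconstruct <- function(sino, grid = ReconGrid(), filt = FilterSpec()) {
  geom <- geometry(sino)
  H <- grid@shape[1]; W <- grid@shape[2]
  spx <- grid@extent[1] / W; spy <- grid@extent[2] / H
  if (abs(spx - spy) > 1e-9)
    stop("reconstruction pixels must be square (extent/shape mismatch)")
  if (sqrt(sum((grid@extent / 2)^2)) >= geom@radius)
    stop("reconstruction grid must lie strictly inside the detector ring")
  b <- backprojectionTerm(sino, filt)
  det <- detectorPositions(geom)[detectorMask(sino), , drop = FALSE]
  coords <- gridCoords(H, W, spx)
  vmmus <- geom@speedOfSound / 1000
  invVdt <- 1 / (vmmus * sino@dt)
  acc <- numeric(H * W)
  for (d in seq_len(nrow(det)))
    .bpAccumulate(acc, b[d, ], coords[, 1], coords[, 2],
                  det[d, 1], det[d, 2], invVdt)
  PressureImage(matrix(acc / nrow(det), H, W), spacing = spx)
}

#' Build a clean/degraded training pair
#'
#' Simulates full-ring acquisition of a phantom, reconstructs the full-view
#' reference x0 and a degraded (sparse- or limited-view) counterpart mu on
#' the same grid, and normalizes both jointly to \[0, 255\] using the
#' full-view image's min/max (the degraded image is clipped into range).
#'
#' @param image the \linkS4class{PressureImage} phantom.
#' @param geom full-ring \linkS4class{RingGeometry}.
#' @param mode "sparse" or "limited" (see [subsampleViews()]).
#' @param param retained element count n, or arc Omega in radians.
#' @param grid a \linkS4class{ReconGrid}.
#' @param filt a \linkS4class{FilterSpec}.
#' @param sino optional precomputed full-view sinogram of `image` (skips the
#'   forward simulation).
#' @return list with elements `x0` and `mu` (\linkS4class{PressureImage}s on
#'   \[0, 255\])
#' @export
makeTrainingPair <- function(image, geom, mode, param, grid = ReconGrid(),
                             filt = FilterSpec(), sino = NULL) {
  if (is.null(sino)) sino <- simulateSignals(image, geom)
  full <- fbpReconstruct(sino, grid, filt)
  deg <- fbpReconstruct(subsampleViews(sino, mode, param), grid, filt)
  fr <- range(pixels(full))
  list(x0 = normalizeToRange(full, from = fr),
       mu = normalizeToRange(deg, from = fr))
}

#' Centroid of the bright feature in a reconstruction
#'
#' First moment of the intensity over the above-half-maximum support, in
#' physical coordinates (mm). Thresholding isolates the reconstructed
#' feature from the bipolar FBP background.
#'
#' @param img a \linkS4class{PressureImage}.
#' @param threshold fraction of the maximum (default 0.5).
#' @return numeric(2) (x, y) in mm
#' @export
featureCentroid <- function(img, threshold = 0.5) {
  p <- pixels(img)
  coords <- gridCoords(nrow(p), ncol(p), spacing(img))
  w <- as.numeric(p)
  w[w < threshold * max(w)] <- 0
  c(x = sum(coords[, 1] * w) / sum(w), y = sum(coords[, 2] * w) / sum(w))
}
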