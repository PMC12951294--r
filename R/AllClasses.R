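#' @useDynLib patrestore, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Two-dimensional initial-pressure image
#'
#' Container for a 2-D map of acoustic initial pressure (or a reconstructed
#' estimate of it) on a regular pixel grid. Reconstructions keep their signed
#' values; dataset images are min--max normalized to the fixed dynamic range
#' \[0, 255\] (see [normalizeToRange()]).
#'
#' @slot pixels numeric matrix (H x W) of intensities, all finite, H, W >= 8.
#' @slot spacing numeric(1), physical pixel pitch in mm.
#' @slot origin numeric(2), physical coordinate (mm) of the grid center,
#'   usually the ring center `c(0, 0)`.
#' @export
setClass("PressureImage",
  representation(pixels = "matrix", spacing = "numeric", origin = "numeric"),
  prototype(spacing = 0.1, origin = c(0, 0))
)

setValidity("PressureImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (nrow(p) < 8L || ncol(p) < 8L) return("image must be at least 8 x 8")
  if (!all(is.finite(p))) return("all intensities must be finite")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    return("spacing must be a single positive number (mm)")
  if (length(object@origin) != 2L || !all(is.finite(object@origin)))
    return("origin must be two finite coordinates (mm)")
  TRUE
})

#' Circular detector array geometry
#'
#' Describes a (possibly partial) ring of ideal point detectors together with
#' the acoustic and sampling parameters of the acquisition. Defaults follow a
#' 512-element full ring of radius 40 mm sampled at 62.5 MHz in soft tissue
#' (speed of sound 1500 m/s).
#'
#' @slot radius numeric(1), ring radius in mm.
#' @slot nElements integer(1), number of detector elements on the arc.
#' @slot coverage numeric(1), angular coverage in radians, in (0, 2*pi].
#' @slot startAngle numeric(1), angle of the first element in radians.
#' @slot speedOfSound numeric(1), m/s.
#' @slot samplingRate numeric(1), MHz.
#' @slot nSamples integer(1), number of time samples per trace.
#' @export
setClass("RingGeometry",
  representation(radius = "numeric", nElements = "integer",
    coverage = "numeric", startAngle = "numeric", speedOfSound = "numeric",
    samplingRate = "numeric", nSamples = "integer")
)

setValidity("RingGeometry", function(object) {
  if (object@radius <= 0) return("radius must be positive")
  if (object@nElements < 1L) return("need at least one detector element")
  if (object@coverage <= 0 || object@coverage > 2 * pi + 1e-12)
    return("coverage must lie in (0, 2*pi]")
  if (object@speedOfSound <= 0) return("speed of sound must be positive")
  if (object@samplingRate <= 0) return("sampling rate must be positive")
  if (object@nSamples < 2L) return("need at least two time samples")
  TRUE
})

#' Sinogram: detector x time pressure traces
#'
#' @slot traces numeric matrix, nDet x nT, one row per active detector.
#' @slot dt numeric(1), sample period in microseconds.
#' @slot geometry the full-ring [RingGeometry-class] the traces were
#'   simulated with.
#' @slot detectorMask logical vector over the full ring's elements marking
#'   which rows are present.
#' @export
setClass("Sinogram",
  representation(traces = "matrix", dt = "numeric", geometry = "RingGeometry",
    detectorMask = "logical")
)

setValidity("Sinogram", function(object) {
  if (!all(is.finite(object@traces))) return("all samples must be finite")
  if (length(object@detectorMask) != object@geometry@nElements)
    return("detectorMask length must equal the ring's element count")
  if (nrow(object@traces) != sum(object@detectorMask))
    return("trace rows must match the number of active detectors")
  if (object@dt <= 0) return("dt must be positive")
  TRUE
})

#' Band-pass filter specification for filtered back-projection
#'
#' Third-order Butterworth band-pass window (0.5--10 MHz by default) applied
#' in the frequency domain, plus the weight of the ramp-derivative term in
#' the back-projection formula (see [backprojectionTerm()]).
#'
#' @slot order integer(1), Butterworth order.
#' @slot band numeric(2), (low, high) cutoffs in MHz.
#' @slot derivativeWeight numeric(1), coefficient of the `t * dp/dt` term;
#'   1 reproduces `b = 2p - t dp/dt`, 2 the universal back-projection variant.
#' @export
setClass("FilterSpec",
  representation(order = "integer", band = "numeric",
    derivativeWeight = "numeric")
)

setValidity("FilterSpec", function(object) {
  if (object@order < 1L) return("order must be >= 1")
  b <- object@band
  if (length(b) != 2L || b[1] <= 0 || b[2] <= b[1])
    return("band must be (low, high) with 0 < low < high")
  TRUE
})

#' Reconstruction grid
#'
#' @slot shape integer(2), (H, W) pixels.
#' @slot extent numeric(2), physical (width, height) in mm; the grid is
#'   centered on the ring center and must lie strictly inside the ring.
#' @export
setClass("ReconGrid",
  representation(shape = "integer", extent = "numeric")
)

setValidity("ReconGrid", function(object) {
  if (length(object@shape) != 2L || any(object@shape < 8L))
    return("shape must be (H, W) with both >= 8")
  if (length(object@extent) != 2L || any(object@extent <= 0))
    return("extent must be positive (width, height) in mm")
  TRUE
})

#' Discretized mean-reverting diffusion schedule
#'
#' Holds the per-state rates theta_t and volatilities sigma_t of the forward
#' mean-reverting SDE `dx = theta_t (mu - x) dt + sigma_t dw`, constrained by
#' `sigma_t^2 / theta_t = 2 lambda^2` so the process has stationary standard
#' deviation lambda, together with the cumulative integral thetaBar used by
#' the closed-form marginals.
#'
#' @slot nStates integer(1), number of diffusion states T (grid has T + 1
#'   points, t_i = i / T, unit time span).
#' @slot lambda numeric(1), stationary noise level in intensity units.
#' @slot theta numeric(T + 1), positive mean-reversion rates on the grid.
#' @slot sigma numeric(T + 1), volatilities, `sigma^2 = 2 lambda^2 theta`.
#' @slot thetaBar numeric(T + 1), cumulative trapezoid integral of theta.
#' @slot dt numeric(1), state spacing 1 / T.
#' @slot kind character(1), shape of the theta ramp ("cosine" or "constant").
#' @export
setClass("DiffusionSchedule",
  representation(nStates = "integer", lambda = "numeric", theta = "numeric",
    sigma = "numeric", thetaBar = "numeric", dt = "numeric",
    kind = "character")
)

setValidity("DiffusionSchedule", function(object) {
  Tn <- object@nStates
  if (Tn < 2L) return("need at least 2 states")
  if (object@lambda <= 0) return("lambda must be positive")
  if (length(object@theta) != Tn + 1L || any(object@theta <= 0))
    return("theta must be positive on all T + 1 grid points")
  if (max(abs(object@sigma^2 / object@theta - 2 * object@lambda^2)) > 1e-8)
    return("sigma^2 / theta must equal 2 lambda^2 at every state")
  if (any(diff(object@thetaBar) <= 0))
    return("thetaBar must be strictly increasing")
  TRUE
})

#' Time-conditioned transformer noise-estimation network
#'
#' A hierarchical encoder--decoder of time-driven transformer blocks
#' (channel-transposed attention + gated convolutional feed-forward) that
#' estimates the standard Gaussian noise injected by the forward diffusion,
#' conditioned on the diffusion state index and the degraded image.
#'
#' @slot config list of architecture hyperparameters (see
#'   [networkConfig()]).
#' @slot params nested list of parameter arrays.
#' @slot step numeric(1), number of optimizer steps taken so far.
#' @export
setClass("NoiseNetwork",
  representation(config = "list", params = "list", step = "numeric"),
  prototype(step = 0)
)
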