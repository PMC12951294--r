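#' Phantom specification
#'
#' Describes a family of random initial-pressure phantoms: isolated point
#' sources, collections of filled disks, or branching vessel trees (a
#' recursive random walk with decreasing width that emulates vascular
#' morphology). Ranges are sampled uniformly per phantom.
#'
#' @param kind one of "point", "disks", "vessels".
#' @param countRange integer (min, max) number of objects (disks or vessel
#'   trees).
#' @param radiusRange (min, max) object radius in mm (disk radius, or root
#'   vessel half-width).
#' @param intensityRange (min, max) object amplitude, arbitrary pressure
#'   units.
#' @param background constant background level added everywhere.
#' @param seed integer seed making the phantom deterministic.
#' @return a validated list of class "PhantomSpec"
#' @examples
#' spec <- PhantomSpec("disks", countRange = c(3, 6), seed = 7)
#' img <- generatePhantom(spec, c(64, 64), spacing = 0.2)
#' @export
PhantomSpec <- function(kind = c("disks", "point", "vessels"),
                        countRange = c(2, 8), radiusRange = c(0.3, 1.5),
                        intensityRange = c(0.5, 1), background = 0,
                        seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(
    "countRange must be non-empty and non-negative" =
      length(countRange) == 2 && countRange[2] >= countRange[1] &&
      countRange[1] >= 0,
    "radiusRange must be non-empty and non-negative" =
      length(radiusRange) == 2 && radiusRange[2] >= radiusRange[1] &&
      radiusRange[1] >= 0,
    "intensityRange must be non-empty and non-negative" =
      length(intensityRange) == 2 && intensityRange[2] >= intensityRange[1] &&
      intensityRange[1] >= 0,
    "background must be non-negative" = background >= 0
  )
  structure(list(kind = kind, countRange = countRange,
                 radiusRange = radiusRange, intensityRange = intensityRange,
                 background = background, seed = as.integer(seed)),
            class = "PhantomSpec")
}

# stamp a filled disk (pixel-center-inside test) onto a pixel matrix,
# combining by max so overlapping objects keep their brightest value
stampDisk <- function(p, coords, cx, cy, r, amp) {
  inside <- (coords[, 1] - cx)^2 + (coords[, 2] - cy)^2 <= r^2
  p[inside] <- pmax(p[inside], amp)
  p
}

# one vessel tree: random walk from (cx, cy) stamping disks of shrinking
# radius; recursive branching. Connectivity is guaranteed because every
# stamp overlaps its predecessor (step < radius) and the radius never drops
# below 1.1 pixels, so consecutive stamps always share edge-adjacent pixels.
walkVessel <- function(p, coords, cx, cy, dir, r, amp, extent, depth,
                       minR) {
  nsteps <- sample(20:45, 1)
  for (i in seq_len(nsteps)) {
    r <- max(r, minR)
    p <- stampDisk(p, coords, cx, cy, r, amp)
    step <- 0.7 * r
    dir <- dir + stats::rnorm(1, 0, 0.35)
    cx <- cx + step * cos(dir)
    cy <- cy + step * sin(dir)
    if (abs(cx) > extent[1] / 2 || abs(cy) > extent[2] / 2) break
    r <- max(r * 0.985, minR)
    if (depth > 0 && stats::runif(1) < 0.08) {
      side <- sample(c(-1, 1), 1)
      p <- walkVessel(p, coords, cx, cy, dir + side * stats::runif(1, 0.5, 1.1),
                      r * 0.7, amp, extent, depth - 1, minR)
    }
  }
  p
}

#' Generate a seeded initial-pressure phantom
#'
#' Deterministic for a fixed spec (including its seed): two calls yield
#' bit-identical images. Point phantoms light exactly one pixel; disk and
#' vessel phantoms place objects uniformly inside the grid with amplitudes
#' in the spec's intensity range.
#'
#' @param spec a [PhantomSpec()].
#' @param grid (H, W) in pixels, both >= 8; a single number gives a square.
#' @param spacing pixel pitch in mm.
#' @return a \linkS4class{PressureImage} (raw amplitudes; use
#'   [normalizeToRange()] for the \[0, 255\] dataset convention)
#' @examples
#' img <- generatePhantom(PhantomSpec("point", seed = 3), 64)
#' sum(pixels(img) > 0)  # exactly 1
#' @export
generatePhantom <- function(spec, grid = c(128L, 128L), spacing = 0.2) {
  stopifnot(inherits(spec, "PhantomSpec"))
  if (length(grid) == 1L) grid <- c(grid, grid)
  if (any(grid < 8L)) stop("grid must be at least 8 x 8")
  H <- as.integer(grid[1]); W <- as.integer(grid[2])
  extent <- c(W, H) * spacing
  coords <- gridCoords(H, W, spacing)
  p <- matrix(spec$background, H, W)
  withSeed(spec$seed, {
    amp <- function() stats::runif(1, spec$intensityRange[1],
                                   spec$intensityRange[2])
    if (spec$kind == "point") {
      r <- sample.int(H, 1); c <- sample.int(W, 1)
      p[r, c] <- amp()
    } else {
      n <- sample(seq(spec$countRange[1], spec$countRange[2]), 1)
      for (i in seq_len(n)) {
        cx <- stats::runif(1, -0.35, 0.35) * extent[1]
        cy <- stats::runif(1, -0.35, 0.35) * extent[2]
        r <- stats::runif(1, spec$radiusRange[1], spec$radiusRange[2])
        if (spec$kind == "disks") {
          pv <- matrix(stampDisk(as.vector(p), coords, cx, cy, r, amp()), H, W)
          p <- pv
        } else {
          dir <- stats::runif(1, 0, 2 * pi)
          pv <- walkVessel(as.vector(p), coords, cx, cy, dir,
                           max(r, 1.5 * spacing), amp(), extent, depth = 3,
                           minR = 1.1 * spacing)
          p <- matrix(pv, H, W)
        }
      }
    }
  })
  PressureImage(p, spacing = spacing)
}

#' Split a dataset into train / validation / test
#'
#' Seeded shuffle followed by a floor allocation: validation and test get
#' `floor(n * fraction)` items each and the remainder goes to training, so
#' the three parts are always a disjoint, exhaustive partition.
#'
#' @param items list (or vector) of samples.
#' @param fractions numeric(3) (train, val, test), summing to 1.
#' @param seed integer seed for the shuffle.
#' @return list with elements `train`, `val`, `test`
#' @examples
#' splitDataset(1:10, c(0.8, 0.1, 0.1), seed = 1)
#' @export
splitDataset <- function(items, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(items) == 0) stop("cannot split an empty dataset")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be (train, val, test) summing to 1")
  n <- length(items)
  nVal <- floor(n * fractions[2])
  nTest <- floor(n * fractions[3])
  nTrain <- n - nVal - nTest
  ord <- withSeed(seed, sample.int(n))
  sel <- function(idx) if (is.list(items)) items[idx] else items[idx]
  list(train = sel(ord[seq_len(nTrain)]),
       val = sel(ord[nTrain + seq_len(nVal)]),
       test = sel(ord[nTrain + nVal + seq_len(nTest)]))
}

#' Generate a phantom dataset
#'
#' Fans `seed` out to per-phantom child seeds by index ([childSeed()]) and
#' min--max normalizes every image to \[0, 255\].
#'
#' @param n number of phantoms.
#' @param kind phantom family, or a vector to alternate between families.
#' @param grid (H, W) pixels.
#' @param spacing mm per pixel.
#' @param seed master seed.
#' @param ... further arguments to [PhantomSpec()].
#' @return list of \linkS4class{PressureImage}
#' @export
makePhantomDataset <- function(n, kind = c("disks", "vessels"),
                               grid = c(128L, 128L), spacing = 0.2,
                               seed = 1L, ...) {
  lapply(seq_len(n), function(i) {
    k <- kind[(i - 1L) %% length(kind) + 1L]
    spec <- PhantomSpec(k, seed = childSeed(seed, i), ...)
    normalizeToRange(generatePhantom(spec, grid, spacing))
  })
}
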