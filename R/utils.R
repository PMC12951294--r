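# evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive a child seed from a master seed
#'
#' Fans one master seed out to reproducible per-item seeds so that items can
#' be generated independently (and in any order) while the whole collection
#' stays a pure function of the master seed.
#'
#' @param master integer master seed.
#' @param index positive integer item index.
#' @return an integer seed in \[1, 2^31 - 2\]
#' @examples
#' childSeed(42, 1:3)
#' @export
childSeed <- function(master, index) {
  m <- 2147483647
  as.integer((as.numeric(master) %% m * 48271 + index * 16807 + 12345) %% m + 1)
}

# normalized cross-correlation of two equal-size arrays
ncc <- function(a, b) {
  a <- as.numeric(a) - mean(a)
  b <- as.numeric(b) - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Min--max normalize an image to a fixed dynamic range
#'
#' Dataset images are kept on the range \[0, 255\] so that the diffusion
#' noise level lambda = 50 is meaningful relative to the intensity scale.
#' When `from` is supplied (e.g. the full-view image's min/max for a jointly
#' normalized training pair), values mapping outside the range are clipped.
#'
#' @param img a \linkS4class{PressureImage}.
#' @param range target (low, high), default c(0, 255).
#' @param from source (min, max) used for the affine map; defaults to the
#'   image's own range.
#' @return a normalized \linkS4class{PressureImage}
#' @examples
#' img <- PressureImage(matrix(rnorm(64 * 64), 64), spacing = 0.2)
#' range(pixels(normalizeToRange(img)))
#' @export
normalizeToRange <- function(img, range = c(0, 255), from = NULL) {
  p <- pixels(img)
  if (is.null(from)) from <- range(p)
  span <- from[2] - from[1]
  if (span <= 0) {
    p[] <- range[1]
  } else {
    p <- clip((p - from[1]) / span, 0, 1) * (range[2] - range[1]) + range[1]
  }
  PressureImage(p, spacing = spacing(img), origin = img@origin)
}
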