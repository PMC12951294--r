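asPixelMatrix <- function(x) if (is(x, "PressureImage")) pixels(x) else x

#' Peak signal-to-noise ratio
#'
#' `PSNR = 20 log10(dataRange) - 10 log10(MSE)` in dB; identical images
#' give `Inf`. The package's dataset convention fixes `dataRange = 255`.
#'
#' @param ref reference image (matrix or \linkS4class{PressureImage}).
#' @param test test image, same shape.
#' @param dataRange dynamic range of the data (default 255).
#' @return PSNR in dB
#' @examples
#' psnr(matrix(0, 8, 8), matrix(0.1, 8, 8), dataRange = 1)  # 20 dB
#' @export
psnr <- function(ref, test, dataRange = 255) {
  ref <- asPixelMatrix(ref); test <- asPixelMatrix(test)
  if (!identical(dim(ref), dim(test))) stop("shape mismatch")
  if (dataRange <= 0) stop("dataRange must be positive")
  mse <- mean((ref - test)^2)
  if (mse == 0) return(Inf)
  20 * log10(dataRange) - 10 * log10(mse)
}

#' Root mean square error
#'
#' @inheritParams psnr
#' @return RMSE in intensity units
#' @export
rmse <- function(ref, test) {
  ref <- asPixelMatrix(ref); test <- asPixelMatrix(test)
  if (!identical(dim(ref), dim(test))) stop("shape mismatch")
  sqrt(mean((ref - test)^2))
}

# separable 2-D Gaussian filtering with symmetric ("reflect") borders
gaussianKernel1d <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

filterSeparable <- function(img, k) {
  half <- (length(k) - 1L) %/% 2L
  refl <- function(n) {
    idx <- c(rev(seq_len(half) + 1L), seq_len(n), n - seq_len(half))
    idx
  }
  conv1 <- function(m) {   # filter down the rows of m
    n <- nrow(m)
    mp <- m[refl(n), , drop = FALSE]
    out <- 0
    for (j in seq_along(k))
      out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with an 11-tap Gaussian window (sigma = 1.5) and the
#' standard stabilizers `C1 = (K1 dataRange)^2`, `C2 = (K2 dataRange)^2`
#' with K1 = 0.01, K2 = 0.03.
#'
#' @inheritParams psnr
#' @param windowSize Gaussian window length (odd, default 11).
#' @param sigma window standard deviation (default 1.5).
#' @param K1,K2 stabilizer constants.
#' @return SSIM in \[-1, 1\]; identical images give 1
#' @export
ssim <- function(ref, test, dataRange = 255, windowSize = 11L, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03) {
  x <- asPixelMatrix(ref); y <- asPixelMatrix(test)
  if (!identical(dim(x), dim(y))) stop("shape mismatch")
  if (windowSize > min(dim(x))) stop("window larger than image")
  k <- gaussianKernel1d(windowSize, sigma)
  C1 <- (K1 * dataRange)^2; C2 <- (K2 * dataRange)^2
  mx <- filterSeparable(x, k); my <- filterSeparable(y, k)
  sxx <- filterSeparable(x * x, k) - mx * mx
  syy <- filterSeparable(y * y, k) - my * my
  sxy <- filterSeparable(x * y, k) - mx * my
  s <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(s)
}

#' Central line profiles
#'
#' Intensity along the horizontal and vertical lines through the image
#' center (row `H %/% 2` and column `W %/% 2`, 1-based), as used to compare
#' restorations against ground truth pixel by pixel.
#'
#' @param img matrix or \linkS4class{PressureImage}.
#' @return list of data.frames `horizontal` (index, intensity; length W)
#'   and `vertical` (length H)
#' @export
lineProfiles <- function(img) {
  p <- asPixelMatrix(img)
  r <- max(nrow(p) %/% 2L, 1L); c <- max(ncol(p) %/% 2L, 1L)
  list(horizontal = data.frame(index = seq_len(ncol(p)),
                               intensity = p[r, ]),
       vertical = data.frame(index = seq_len(nrow(p)),
                             intensity = p[, c]))
}

#' Evaluate restored images against references
#'
#' @param refs list of reference images.
#' @param tests list of test images, same length and shapes.
#' @param dataRange dynamic range (default 255).
#' @return list with a per-image data.frame `perImage` (psnr, rmse, ssim)
#'   and a `summary` data.frame of means and standard deviations
#' @export
evaluatePairs <- function(refs, tests, dataRange = 255) {
  stopifnot(length(refs) == length(tests), length(refs) > 0)
  per <- do.call(rbind, lapply(seq_along(refs), function(i) {
    data.frame(image = i,
               psnr = psnr(refs[[i]], tests[[i]], dataRange),
               rmse = rmse(refs[[i]], tests[[i]]),
               ssim = ssim(refs[[i]], tests[[i]], dataRange))
  }))
  fin <- per$psnr[is.finite(per$psnr)]
  list(perImage = per,
       summary = data.frame(
         metric = c("psnr", "rmse", "ssim"),
         mean = c(mean(fin), mean(per$rmse), mean(per$ssim)),
         sd = c(stats::sd(fin), stats::sd(per$rmse), stats::sd(per$ssim))))
}
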