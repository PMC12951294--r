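# Low-level differentiable operations for the noise network.
#
# Feature maps are (H*W) x C matrices (pixels column-major). Every forward
# helper returns what its paired backward needs; backwards return the input
# gradient and parameter gradients. All convolutions are bias-free, which
# makes zero inputs propagate to zero outputs and follows the
# transposed-attention precedent.

# GELU (tanh approximation); scalar/vector inputs take the R path, matrices
# the compiled one
geluFwd <- function(x) {
  if (is.matrix(x)) return(.geluForward(x))
  k <- sqrt(2 / pi)
  0.5 * x * (1 + tanh(k * (x + 0.044715 * x^3)))
}

geluBwd <- function(x, dy) {
  if (is.matrix(x)) return(.geluBackward(x, dy))
  k <- sqrt(2 / pi)
  u <- k * (x + 0.044715 * x^3)
  t <- tanh(u)
  dy * (0.5 * (1 + t) + 0.5 * x * (1 - t^2) * k * (1 + 3 * 0.044715 * x^2))
}

# scale columns of an n x C matrix by a length-C vector
colScale <- function(X, w) .colScaleCpp(X, w)

# bias-free layer normalization over channels, learnable per-channel weight
lnForward <- function(X, w, eps = 1e-6) .lnForwardCpp(X, w, eps)

lnBackward <- function(cache, w, dY) .lnBackwardCpp(cache$xhat, cache$inv,
                                                   w, dY)

# row-wise softmax of a small square matrix and its backward
softmaxRows <- function(Z) {
  e <- exp(Z - Z[cbind(seq_len(nrow(Z)), max.col(Z, "first"))])
  e / rowSums(e)
}

softmaxRowsBwd <- function(S, dS) S * (dS - rowSums(dS * S))

# pixel-unshuffle index maps: for an H x W grid (H, W even), four index
# vectors over the (H/2 x W/2) output, one per 2x2 sub-position
unshuffleIdx <- function(H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  r2 <- rep(seq_len(H2), times = W2)
  c2 <- rep(seq_len(W2), each = H2)
  lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(o) {
    (2L * c2 - 2L + o[2]) * H + (2L * r2 - 1L + o[1])
  })
}

# X: (H*W) x C -> (H*W/4) x 4C, channel blocks ordered by sub-position
pixelUnshuffle <- function(X, H, W) {
  idx <- unshuffleIdx(H, W)
  cbind(X[idx[[1]], , drop = FALSE], X[idx[[2]], , drop = FALSE],
        X[idx[[3]], , drop = FALSE], X[idx[[4]], , drop = FALSE])
}

pixelUnshuffleBwd <- function(dY, H, W, C) {
  idx <- unshuffleIdx(H, W)
  dX <- matrix(0, H * W, C)
  for (k in 1:4)
    dX[idx[[k]], ] <- dY[, (k - 1L) * C + seq_len(C), drop = FALSE]
  dX
}

# X: (H*W/4) x 4C -> (H*W) x C on the doubled grid (H, W are OUTPUT dims)
pixelShuffle <- function(X, H, W) {
  C <- ncol(X) %/% 4L
  idx <- unshuffleIdx(H, W)
  Y <- matrix(0, H * W, C)
  for (k in 1:4)
    Y[idx[[k]], ] <- X[, (k - 1L) * C + seq_len(C), drop = FALSE]
  Y
}

pixelShuffleBwd <- function(dY, H, W) {
  idx <- unshuffleIdx(H, W)
  cbind(dY[idx[[1]], , drop = FALSE], dY[idx[[2]], , drop = FALSE],
        dY[idx[[3]], , drop = FALSE], dY[idx[[4]], , drop = FALSE])
}

#' Sinusoidal embedding of a diffusion state index
#'
#' Standard geometric-frequency sine/cosine embedding; each block passes it
#' through its own two-layer perceptron to produce channel-wise scale and
#' shift arrays.
#'
#' @param t state index (scalar, in \[0, T\]).
#' @param dim embedding length (even).
#' @return numeric vector of length `dim`
#' @examples
#' timeEmbedding(5, 16)
#' @export
timeEmbedding <- function(t, dim = 32L) {
  if (dim %% 2L != 0L) stop("embedding dim must be even")
  half <- dim %/% 2L
  freq <- exp(-log(10000) * (seq_len(half) - 1) / max(half - 1, 1))
  c(sin(t * freq), cos(t * freq))
}

# per-block time perceptron: emb -> GELU(emb W1 + b1) W2 + b2
timeMlpFwd <- function(emb, p) {
  h1 <- drop(emb %*% p$tW1) + p$tb1
  a1 <- geluFwd(h1)
  list(out = drop(a1 %*% p$tW2) + p$tb2, h1 = h1, a1 = a1)
}

timeMlpBwd <- function(cache, emb, p, dout) {
  da1 <- drop(p$tW2 %*% dout)
  dh1 <- geluBwd(cache$h1, da1)
  list(dtW2 = outer(cache$a1, dout), dtb2 = dout,
       dtW1 = outer(emb, dh1), dtb1 = dh1)
}
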