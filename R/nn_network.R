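#' Noise-network architecture configuration
#'
#' The network is a 5-level hierarchy of time-driven transformer blocks:
#' three encoder levels with pixel-unshuffle down-sampling (channel widths
#' C, 2C, 4C), a bottleneck at width 8C, three mirrored decoder levels with
#' pixel-shuffle up-sampling and skip concatenation, and a refinement stage
#' at full resolution. `blocks` and `heads` give one entry per level in the
#' order (level 1, level 2, level 3, bottleneck, refinement); encoder and
#' decoder share the per-level counts.
#'
#' @param baseChannels C, width of the first level (16 for desk scale,
#'   48 for full runs).
#' @param blocks integer(5) blocks per level.
#' @param heads integer(5) attention heads per level; each must divide the
#'   level's width.
#' @param expansion GCFN hidden-width expansion factor (default 2.66).
#' @param timeDim sinusoidal time-embedding length (default 32).
#' @param inChannels input channels (2: the state x_t concatenated with the
#'   degraded image mu).
#' @param inputScale optional intensity divisor applied before the shallow
#'   embedding (inputs enter as `x / inputScale`); the default 1 feeds raw
#'   intensities, which trains measurably better here than unit-range
#'   scaling because the bias-free layer-normalized blocks are nearly
#'   scale-equivariant and the raw difference `x_t - mu` carries the
#'   signal the noise estimate needs.
#' @return a validated config list
#' @examples
#' cfg <- networkConfig(baseChannels = 8L, heads = c(1, 2, 2, 4, 1))
#' @export
networkConfig <- function(baseChannels = 16L, blocks = c(1L, 1L, 1L, 1L, 1L),
                          heads = c(1L, 2L, 4L, 8L, 1L), expansion = 2.66,
                          timeDim = 32L, inChannels = 2L,
                          inputScale = 1) {
  C <- as.integer(baseChannels)
  blocks <- as.integer(blocks); heads <- as.integer(heads)
  stopifnot(length(blocks) == 5L, length(heads) == 5L, all(blocks >= 1L),
            all(heads >= 1L), C >= 1L, expansion > 0, timeDim %% 2L == 0L)
  widths <- c(C, 2L * C, 4L * C, 8L * C, C)
  if (any(widths %% heads != 0L))
    stop("every level width must be divisible by its head count")
  list(baseChannels = C, blocks = blocks, heads = heads,
       expansion = expansion, timeDim = as.integer(timeDim),
       inChannels = as.integer(inChannels), inputScale = inputScale,
       widths = widths)
}

gcfnHidden <- function(C, expansion) max(1L, as.integer(round(C * expansion)))

rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

initBlock <- function(C, heads, expansion, timeDim, residScale = 1) {
  hd <- gcfnHidden(C, expansion)
  list(
    ln1 = rep(1, C),
    attn = list(
      Wq = rmat(C, C, 1 / sqrt(C)), Kq = rmat(9, C, 1 / 3),
      Wk = rmat(C, C, 1 / sqrt(C)), Kk = rmat(9, C, 1 / 3),
      Wv = rmat(C, C, 1 / sqrt(C)), Kv = rmat(9, C, 1 / 3),
      Wp = rmat(C, C, residScale / sqrt(C)),
      alpha = rep(sqrt(C / heads), heads),
      tW1 = rmat(timeDim, timeDim, 1 / sqrt(timeDim)),
      tb1 = rep(0, timeDim),
      tW2 = matrix(0, timeDim, 6 * C),   # modulation starts at identity
      tb2 = rep(0, 6 * C)),
    ln2 = rep(1, C),
    ffn = list(
      Wc1 = rmat(C, hd, 1 / sqrt(C)), K1 = rmat(9, hd, 1 / 3),
      Wc2 = rmat(C, hd, 1 / sqrt(C)), K2 = rmat(9, hd, 1 / 3),
      Wc3 = rmat(hd, C, residScale / sqrt(hd))))
}

initStage <- function(nBlocks, C, heads, expansion, timeDim,
                      residScale = 1) {
  lapply(seq_len(nBlocks),
         function(i) initBlock(C, heads, expansion, timeDim, residScale))
}

#' Initialize a noise network
#'
#' Weights are drawn from scaled Gaussians (seeded); the output projection
#' and the time-modulation output layers start at zero so the freshly
#' initialized network predicts zero noise and modulation starts at
#' identity.
#'
#' @param config a [networkConfig()].
#' @param seed integer seed for the weight draws.
#' @param residScale multiplier on the initialization of each block's
#'   residual-branch output kernels (the attention projection and the
#'   feed-forward output); values below 1 start the network closer to the
#'   identity, which stabilizes short training runs.
#' @return a \linkS4class{NoiseNetwork}
#' @examples
#' net <- initNoiseNetwork(networkConfig(baseChannels = 8L,
#'                                       heads = c(1, 2, 2, 4, 1)))
#' countParameters(net)
#' @export
initNoiseNetwork <- function(config = networkConfig(), seed = 1L,
                             residScale = 1) {
  C <- config$baseChannels
  w <- config$widths
  e <- config$expansion; td <- config$timeDim; b <- config$blocks
  h <- config$heads
  params <- withSeed(seed, list(
    patch = list(W = rmat(9 * config$inChannels, C,
                          1 / sqrt(9 * config$inChannels))),
    enc1 = initStage(b[1], w[1], h[1], e, td, residScale),
    down1 = list(W = rmat(w[1], w[1] %/% 2L, 1 / sqrt(w[1]))),
    enc2 = initStage(b[2], w[2], h[2], e, td, residScale),
    down2 = list(W = rmat(w[2], w[2] %/% 2L, 1 / sqrt(w[2]))),
    enc3 = initStage(b[3], w[3], h[3], e, td, residScale),
    down3 = list(W = rmat(w[3], w[3] %/% 2L, 1 / sqrt(w[3]))),
    latent = initStage(b[4], w[4], h[4], e, td, residScale),
    up3 = list(W = rmat(w[4], 2L * w[4], 1 / sqrt(w[4]))),
    red3 = list(W = rmat(2L * w[3], w[3], 1 / sqrt(2 * w[3]))),
    dec3 = initStage(b[3], w[3], h[3], e, td, residScale),
    up2 = list(W = rmat(w[3], 2L * w[3], 1 / sqrt(w[3]))),
    red2 = list(W = rmat(2L * w[2], w[2], 1 / sqrt(2 * w[2]))),
    dec2 = initStage(b[2], w[2], h[2], e, td, residScale),
    up1 = list(W = rmat(w[2], 2L * w[2], 1 / sqrt(w[2]))),
    red1 = list(W = rmat(2L * w[1], w[1], 1 / sqrt(2 * w[1]))),
    dec1 = initStage(b[1], w[1], h[1], e, td, residScale),
    refine = initStage(b[5], w[5], h[5], e, td, residScale),
    out = list(W = matrix(0, 9 * C, 1))))
  new("NoiseNetwork", config = config, params = params, step = 0)
}

setMethod("show", "NoiseNetwork", function(object) {
  cfg <- object@config
  cat(sprintf(
    "NoiseNetwork: C = %d, blocks [%s], heads [%s], %s parameters\n",
    cfg$baseChannels, paste(cfg$blocks, collapse = ","),
    paste(cfg$heads, collapse = ","),
    format(countParameters(object), big.mark = ",")))
  cat(sprintf("  trained for %d steps\n", as.integer(object@step)))
})

# pad a (H*W) vectorized image pair up to multiples of 8 (zero padding),
# returning padded matrices and the crop info
padTo8 <- function(x) {
  H <- nrow(x); W <- ncol(x)
  H2 <- 8L * ((H + 7L) %/% 8L); W2 <- 8L * ((W + 7L) %/% 8L)
  if (H2 == H && W2 == W) return(list(x = x, H = H, W = W, crop = FALSE))
  xp <- matrix(0, H2, W2)
  xp[seq_len(H), seq_len(W)] <- x
  list(x = xp, H = H2, W = W2, crop = TRUE, H0 = H, W0 = W)
}

# full forward pass; x and mu are H x W matrices. Returns the estimated
# noise field and (optionally) the cache for backprop.
networkForward <- function(params, config, x, mu, t, keepCache = FALSE) {
  sc <- config$inputScale
  if (is.null(sc) || sc == 1) {
    px <- padTo8(x); pm <- padTo8(mu)
  } else {
    px <- padTo8(x / sc); pm <- padTo8(mu / sc)
  }
  H <- px$H; W <- px$W
  temb <- timeEmbedding(t, config$timeDim)
  hds <- config$heads
  X0 <- cbind(as.numeric(px$x), as.numeric(pm$x))
  F0 <- .im2col3x3(X0, H, W) %*% params$patch$W
  e1 <- stageForward(F0, H, W, params$enc1, temb, hds[1])
  d1 <- pixelUnshuffle(e1$out %*% params$down1$W, H, W)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  e2 <- stageForward(d1, H2, W2, params$enc2, temb, hds[2])
  d2 <- pixelUnshuffle(e2$out %*% params$down2$W, H2, W2)
  H3 <- H2 %/% 2L; W3 <- W2 %/% 2L
  e3 <- stageForward(d2, H3, W3, params$enc3, temb, hds[3])
  d3 <- pixelUnshuffle(e3$out %*% params$down3$W, H3, W3)
  H4 <- H3 %/% 2L; W4 <- W3 %/% 2L
  lt <- stageForward(d3, H4, W4, params$latent, temb, hds[4])
  u3in <- lt$out %*% params$up3$W
  u3 <- pixelShuffle(u3in, H3, W3)
  c3 <- cbind(u3, e3$out) %*% params$red3$W
  s3 <- stageForward(c3, H3, W3, params$dec3, temb, hds[3])
  u2 <- pixelShuffle(s3$out %*% params$up2$W, H2, W2)
  c2 <- cbind(u2, e2$out) %*% params$red2$W
  s2 <- stageForward(c2, H2, W2, params$dec2, temb, hds[2])
  u1 <- pixelShuffle(s2$out %*% params$up1$W, H, W)
  c1 <- cbind(u1, e1$out) %*% params$red1$W
  s1 <- stageForward(c1, H, W, params$dec1, temb, hds[1])
  rf <- stageForward(s1$out, H, W, params$refine, temb, hds[5])
  rfCol <- .im2col3x3(rf$out, H, W)
  out <- matrix(rfCol %*% params$out$W, H, W)
  if (px$crop) out <- out[seq_len(px$H0), seq_len(px$W0), drop = FALSE]
  if (!keepCache) return(list(out = out))
  list(out = out,
       cache = list(X0 = X0, F0 = F0, e1 = e1, d1 = d1, e2 = e2, d2 = d2,
                    e3 = e3, d3 = d3, lt = lt, u3 = u3, c3 = c3, s3 = s3,
                    u2 = u2, c2 = c2, s2 = s2, u1 = u1, c1 = c1, s1 = s1,
                    rf = rf, rfCol = rfCol, temb = temb,
                    H = H, W = W, pad = px))
}

# backward pass: dOut is the gradient wrt the (cropped) output field.
# Returns the parameter gradient tree (input gradients are discarded).
networkBackward <- function(params, config, cache, dOut) {
  H <- cache$H; W <- cache$W
  hds <- config$heads
  temb <- cache$temb
  if (cache$pad$crop) {
    dPad <- matrix(0, H, W)
    dPad[seq_len(cache$pad$H0), seq_len(cache$pad$W0)] <- dOut
    dOut <- dPad
  }
  g <- list()
  dv <- as.numeric(dOut)
  g$out <- list(W = crossprod(cache$rfCol, dv))
  dRf <- .col2im3x3(tcrossprod(matrix(dv, ncol = 1L), params$out$W), H, W,
                    config$widths[5])
  rb <- stageBackward(cache$rf$caches, params$refine, temb, hds[5], dRf)
  g$refine <- rb$grads
  b1 <- stageBackward(cache$s1$caches, params$dec1, temb, hds[1], rb$dX)
  g$dec1 <- b1$grads
  dc1in <- tcrossprod(b1$dX, params$red1$W)
  g$red1 <- list(W = crossprod(cbind(cache$u1, cache$e1$out), b1$dX))
  C1 <- ncol(cache$u1)
  du1 <- dc1in[, seq_len(C1), drop = FALSE]
  dSkip1 <- dc1in[, C1 + seq_len(ncol(cache$e1$out)), drop = FALSE]
  du1in <- pixelShuffleBwd(du1, H, W)
  g$up1 <- list(W = crossprod(cache$s2$out, du1in))
  dS2 <- tcrossprod(du1in, params$up1$W)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  b2 <- stageBackward(cache$s2$caches, params$dec2, temb, hds[2], dS2)
  g$dec2 <- b2$grads
  dc2in <- tcrossprod(b2$dX, params$red2$W)
  g$red2 <- list(W = crossprod(cbind(cache$u2, cache$e2$out), b2$dX))
  C2 <- ncol(cache$u2)
  du2 <- dc2in[, seq_len(C2), drop = FALSE]
  dSkip2 <- dc2in[, C2 + seq_len(ncol(cache$e2$out)), drop = FALSE]
  du2in <- pixelShuffleBwd(du2, H2, W2)
  g$up2 <- list(W = crossprod(cache$s3$out, du2in))
  dS3 <- tcrossprod(du2in, params$up2$W)
  H3 <- H2 %/% 2L; W3 <- W2 %/% 2L
  b3 <- stageBackward(cache$s3$caches, params$dec3, temb, hds[3], dS3)
  g$dec3 <- b3$grads
  dc3in <- tcrossprod(b3$dX, params$red3$W)
  g$red3 <- list(W = crossprod(cbind(cache$u3, cache$e3$out), b3$dX))
  C3 <- ncol(cache$u3)
  du3 <- dc3in[, seq_len(C3), drop = FALSE]
  dSkip3 <- dc3in[, C3 + seq_len(ncol(cache$e3$out)), drop = FALSE]
  du3in <- pixelShuffleBwd(du3, H3, W3)
  g$up3 <- list(W = crossprod(cache$lt$out, du3in))
  dLt <- tcrossprod(du3in, params$up3$W)
  H4 <- H3 %/% 2L; W4 <- W3 %/% 2L
  bl <- stageBackward(cache$lt$caches, params$latent, temb, hds[4], dLt)
  g$latent <- bl$grads
  dD3 <- bl$dX
  dE3out <- pixelUnshuffleBwd(dD3, H3, W3, ncol(params$down3$W))
  g$down3 <- list(W = crossprod(cache$e3$out, dE3out))
  dE3 <- tcrossprod(dE3out, params$down3$W) + dSkip3
  be3 <- stageBackward(cache$e3$caches, params$enc3, temb, hds[3], dE3)
  g$enc3 <- be3$grads
  dE2out <- pixelUnshuffleBwd(be3$dX, H2, W2, ncol(params$down2$W))
  g$down2 <- list(W = crossprod(cache$e2$out, dE2out))
  dE2 <- tcrossprod(dE2out, params$down2$W) + dSkip2
  be2 <- stageBackward(cache$e2$caches, params$enc2, temb, hds[2], dE2)
  g$enc2 <- be2$grads
  dE1out <- pixelUnshuffleBwd(be2$dX, H, W, ncol(params$down1$W))
  g$down1 <- list(W = crossprod(cache$e1$out, dE1out))
  dE1 <- tcrossprod(dE1out, params$down1$W) + dSkip1
  be1 <- stageBackward(cache$e1$caches, params$enc1, temb, hds[1], dE1)
  g$enc1 <- be1$grads
  dF0 <- be1$dX
  g$patch <- list(W = crossprod(.im2col3x3(cache$X0, H, W), dF0))
  g
}

#' Estimate the injected noise for one state
#'
#' Runs the network forward on the state/conditioning pair. Deterministic:
#' fixed weights and inputs give bit-identical output.
#'
#' @param net a \linkS4class{NoiseNetwork}.
#' @param x current state (H x W matrix or \linkS4class{PressureImage}).
#' @param mu degraded conditioning image, same shape.
#' @param t diffusion state index.
#' @return H x W matrix of estimated noise
#' @export
predictNoise <- function(net, x, mu, t) {
  if (is(x, "PressureImage")) x <- pixels(x)
  if (is(mu, "PressureImage")) mu <- pixels(mu)
  if (!identical(dim(x), dim(mu))) stop("x and mu must have the same shape")
  networkForward(net@params, net@config, x, mu, t)$out
}

#' Count network parameters
#'
#' Walks the parameter tree and sums the length of every array.
#'
#' @param net a \linkS4class{NoiseNetwork} (or a raw parameter tree).
#' @return integer total
#' @export
countParameters <- function(net) {
  p <- if (is(net, "NoiseNetwork")) net@params else net
  count <- function(x) {
    if (is.list(x)) sum(vapply(x, count, numeric(1))) else length(x)
  }
  as.integer(count(p))
}

#' Closed-form parameter counts
#'
#' `tmtaParameterCount` gives the kernel parameter count of one TMTA unit at
#' width C: `3 (C^2 + 9C)` for the Q/K/V branch convolutions plus `C^2` for
#' the output projection; with `includeTime = TRUE` the per-head
#' temperatures and the time perceptron (`timeDim^2 + timeDim` hidden layer
#' plus `timeDim * 6C + 6C` modulation output) are added.
#' `gcfnParameterCount` covers the gated feed-forward at expansion `e`
#' (hidden width `round(e C)`). `standardBlockParameterCount` is the
#' matched-width conventional transformer block used for comparison: four
#' full C x C attention projections plus a dense feed-forward with 4x
#' expansion (`12 C^2` in total, bias-free).
#'
#' @param C channel width.
#' @param heads attention heads.
#' @param timeDim time-embedding length.
#' @param includeTime include temperature and time-perceptron parameters.
#' @param expansion GCFN expansion factor.
#' @return integer parameter count
#' @examples
#' tmtaParameterCount(16)            # 1456 kernel parameters
#' @export
tmtaParameterCount <- function(C, heads = 1L, timeDim = 32L,
                               includeTime = FALSE) {
  kernels <- 3 * (C^2 + 9 * C) + C^2
  if (!includeTime) return(as.integer(kernels))
  as.integer(kernels + heads + timeDim^2 + timeDim + timeDim * 6 * C + 6 * C)
}

#' @rdname tmtaParameterCount
#' @export
gcfnParameterCount <- function(C, expansion = 2.66) {
  hd <- gcfnHidden(C, expansion)
  as.integer(2 * C * hd + 2 * 9 * hd + hd * C)
}

#' @rdname tmtaParameterCount
#' @export
standardBlockParameterCount <- function(C) as.integer(12 * C^2)

# closed-form count of one full block (including norms and time path)
blockParameterCount <- function(C, heads, expansion, timeDim) {
  tmtaParameterCount(C, heads, timeDim, includeTime = TRUE) +
    gcfnParameterCount(C, expansion) + 2 * C
}

#' Closed-form total parameter count of a network configuration
#'
#' Computed purely from the architecture arithmetic, independently of the
#' initialized arrays; must agree exactly with [countParameters()] on the
#' initialized network.
#'
#' @param config a [networkConfig()].
#' @return integer total
#' @export
closedFormParameterCount <- function(config) {
  w <- config$widths; b <- config$blocks; h <- config$heads
  e <- config$expansion; td <- config$timeDim
  C <- config$baseChannels
  stages <- sum(vapply(seq_len(5), function(l) {
    b[l] * blockParameterCount(w[l], h[l], e, td)
  }, numeric(1))) +
    b[3] * blockParameterCount(w[3], h[3], e, td) +   # decoder mirrors
    b[2] * blockParameterCount(w[2], h[2], e, td) +
    b[1] * blockParameterCount(w[1], h[1], e, td)
  samplers <- w[1] * (w[1] %/% 2L) + w[2] * (w[2] %/% 2L) +
    w[3] * (w[3] %/% 2L) +                            # down
    w[4] * 2L * w[4] + w[3] * 2L * w[3] + w[2] * 2L * w[2] +  # up
    2L * w[3] * w[3] + 2L * w[2] * w[2] + 2L * w[1] * w[1]    # reduce
  io <- 9L * config$inChannels * C + 9L * C
  as.integer(stages + samplers + io)
}
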