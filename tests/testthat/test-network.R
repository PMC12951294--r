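smallConfig <- function() networkConfig(baseChannels = 4L,
                                        heads = c(1L, 2L, 2L, 4L, 1L),
                                        expansion = 2, timeDim = 8L)

test_that("time embeddings are deterministic, sized, and injective on the grid", {
  e1 <- timeEmbedding(5, 32L)
  expect_identical(e1, timeEmbedding(5, 32L))
  expect_length(e1, 32L)
  expect_gt(sqrt(sum((timeEmbedding(0, 32L) - timeEmbedding(200, 32L))^2)), 0)
  expect_error(timeEmbedding(1, 7L), "even")
})

test_that("transposed attention preserves shape and is row-stochastic", {
  set.seed(20)
  cfg <- smallConfig()
  net <- initNoiseNetwork(cfg, seed = 1)
  p <- net@params$enc2[[1]]$attn     # width 8, 2 heads
  X <- matrix(rnorm(16 * 16 * 8), 256, 8)
  r <- tmtaForward(X, 16, 16, p, timeEmbedding(3, 8L), heads = 2L)
  expect_identical(dim(r$out), dim(X))
  for (S in r$cache$S) {
    expect_identical(dim(S), c(4L, 4L))
    expect_lt(max(abs(rowSums(S) - 1)), 1e-6)
  }
  expect_error(tmtaForward(X, 16, 16, p, timeEmbedding(3, 8L), heads = 3L),
               "divisible")
})

test_that("attention on a single pixel matches the hand-computed matrix chain", {
  # HW = 1, C = 2, one head: every operation reduces to small matrix
  # arithmetic that can be written out explicitly
  C <- 2L; td <- 4L
  p <- list(Wq = matrix(c(0.3, -0.2, 0.5, 0.1), 2), Kq = matrix(0, 9, 2),
            Wk = matrix(c(-0.4, 0.6, 0.2, 0.3), 2), Kk = matrix(0, 9, 2),
            Wv = matrix(c(0.7, 0.1, -0.3, 0.4), 2), Kv = matrix(0, 9, 2),
            Wp = matrix(c(1.1, -0.5, 0.2, 0.8), 2), alpha = 1.3,
            tW1 = matrix(0.1, td, td), tb1 = rep(0.2, td),
            tW2 = matrix(0.05, td, 12), tb2 = rep(-0.1, 12))
  p$Kq[5, ] <- c(0.9, 1.1); p$Kk[5, ] <- c(1.2, 0.8); p$Kv[5, ] <- c(1, 1)
  X <- matrix(c(0.6, -1.2), 1, 2)
  temb <- timeEmbedding(7, td)
  r <- tmtaForward(X, 1L, 1L, p, temb, heads = 1L)

  # hand evaluation
  h1 <- drop(temb %*% p$tW1) + p$tb1
  gelu <- function(z) 0.5 * z * (1 + tanh(sqrt(2 / pi) *
                                            (z + 0.044715 * z^3)))
  mod <- drop(gelu(h1) %*% p$tW2) + p$tb2
  gb <- matrix(mod, nrow = 2)
  q <- (X * (gb[, 1] + 1) + gb[, 2]) %*% p$Wq * p$Kq[5, ]
  k <- (X * (gb[, 3] + 1) + gb[, 4]) %*% p$Wk * p$Kk[5, ]
  v <- (X * (gb[, 5] + 1) + gb[, 6]) %*% p$Wv * p$Kv[5, ]
  Z <- t(k) %*% q / p$alpha
  S <- exp(Z) / rowSums(exp(Z))
  expected <- (v %*% S) %*% p$Wp
  expect_lt(max(abs(r$out - expected)), 1e-6)
})

test_that("the gated feed-forward matches direct evaluation and kills zero input", {
  set.seed(21)
  hd <- 5L
  p <- list(Wc1 = matrix(rnorm(2 * hd, 0, 0.5), 2, hd),
            K1 = matrix(rnorm(9 * hd, 0, 0.3), 9, hd),
            Wc2 = matrix(rnorm(2 * hd, 0, 0.5), 2, hd),
            K2 = matrix(rnorm(9 * hd, 0, 0.3), 9, hd),
            Wc3 = matrix(rnorm(hd * 2, 0, 0.5), hd, 2))
  zero <- gcfnForward(matrix(0, 4, 2), 2, 2, p)
  expect_true(all(zero$out == 0))

  X <- matrix(rnorm(8, 0, 0.8), 4, 2)   # 2 x 2 spatial, C = 2
  r <- gcfnForward(X, 2L, 2L, p)
  expect_identical(dim(r$out), dim(X))

  # direct evaluation with explicit spatial loops
  dwRef <- function(M, K) {
    out <- matrix(0, 4, ncol(M))
    for (ch in seq_len(ncol(M))) {
      img <- matrix(M[, ch], 2, 2)
      o <- matrix(0, 2, 2)
      for (rr in 1:2) for (cc in 1:2) {
        acc <- 0
        for (dr in -1:1) for (dc in -1:1) {
          r2 <- rr + dr; c2 <- cc + dc
          if (r2 >= 1 && r2 <= 2 && c2 >= 1 && c2 <= 2)
            acc <- acc + img[r2, c2] * K[(dr + 1) + 3 * (dc + 1) + 1, ch]
        }
        o[rr, cc] <- acc
      }
      out[, ch] <- as.numeric(o)
    }
    out
  }
  gelu <- function(z) 0.5 * z * (1 + tanh(sqrt(2 / pi) *
                                            (z + 0.044715 * z^3)))
  expected <- (gelu(dwRef(X %*% p$Wc1, p$K1)) *
                 dwRef(X %*% p$Wc2, p$K2)) %*% p$Wc3
  expect_lt(max(abs(r$out - expected)), 1e-6)
})

test_that("the full network preserves spatial shape, pads odd sizes, and is deterministic", {
  cfg <- smallConfig()
  net <- initNoiseNetwork(cfg, seed = 4)
  for (n in c(64L, 96L, 44L)) {
    x <- matrix(rnorm(n * n, 100, 40), n, n)
    mu <- matrix(rnorm(n * n, 100, 40), n, n)
    out <- predictNoise(net, x, mu, 10)
    expect_identical(dim(out), c(n, n))
  }
  x <- matrix(rnorm(32 * 32, 100, 40), 32, 32)
  mu <- matrix(rnorm(32 * 32, 100, 40), 32, 32)
  expect_identical(predictNoise(net, x, mu, 3), predictNoise(net, x, mu, 3))
  expect_error(predictNoise(net, x, mu[1:16, 1:16], 3), "same shape")
})

test_that("backpropagation matches finite differences on sampled parameters", {
  cfg <- smallConfig()
  net <- initNoiseNetwork(cfg, seed = 3)
  # randomize the zero-initialized layers so every path carries gradient
  rnd <- function(p) if (is.list(p)) lapply(p, rnd) else
    p + rnorm(length(p), 0, 0.05)
  set.seed(30)
  params <- rnd(net@params)
  x <- matrix(rnorm(64, 100, 40), 8, 8)
  mu <- matrix(rnorm(64, 100, 30), 8, 8)
  eps <- matrix(rnorm(64), 8, 8)
  lossFn <- function(pp) {
    out <- patrestore:::networkForward(pp, cfg, x, mu, 5)$out
    mean((out - eps)^2)
  }
  fw <- patrestore:::networkForward(params, cfg, x, mu, 5, keepCache = TRUE)
  g <- patrestore:::networkBackward(params, cfg, fw$cache,
                                    2 * (fw$out - eps) / 64)
  paths <- function(p, pre = character()) {
    if (!is.list(p)) return(list(pre))
    unlist(lapply(seq_along(p), function(i) {
      nm <- if (!is.null(names(p)) && nzchar(names(p)[i])) names(p)[i]
            else as.character(i)
      paths(p[[i]], c(pre, nm))
    }), recursive = FALSE)
  }
  getL <- function(p, pa) {
    for (k in pa) {
      if (grepl("^[0-9]+$", k)) k <- as.integer(k)
      p <- p[[k]]
    }
    p
  }
  setL <- function(p, pa, v) {
    k <- pa[1]
    if (grepl("^[0-9]+$", k)) k <- as.integer(k)
    if (length(pa) == 1) { p[[k]] <- v; return(p) }
    p[[k]] <- setL(p[[k]], pa[-1], v)
    p
  }
  allPaths <- paths(params)
  set.seed(31)
  checked <- 0L
  for (pa in sample(allPaths, 40)) {
    leaf <- getL(params, pa); gl <- getL(g, pa)
    expect_identical(length(leaf), length(gl))
    j <- sample.int(length(leaf), 1)
    h <- 1e-5 * max(1, abs(leaf[j]))
    lp <- leaf; lp[j] <- leaf[j] + h
    lm <- leaf; lm[j] <- leaf[j] - h
    fd <- (lossFn(setL(params, pa, lp)) - lossFn(setL(params, pa, lm))) /
      (2 * h)
    # mixed tolerance: tight relative check with an absolute floor that
    # covers finite-difference noise on near-zero gradients
    expect_lt(abs(fd - gl[j]) / max(abs(fd), abs(gl[j]), 0.01), 1e-4)
    checked <- checked + 1L
  }
  expect_identical(checked, 40L)
})

test_that("every parameter tensor receives gradient from the training loss", {
  cfg <- smallConfig()
  net <- initNoiseNetwork(cfg, seed = 6)
  rnd <- function(p) if (is.list(p)) lapply(p, rnd) else
    p + rnorm(length(p), 0, 0.05)
  set.seed(32)
  params <- rnd(net@params)
  x <- matrix(rnorm(256, 100, 40), 16, 16)
  mu <- matrix(rnorm(256, 100, 30), 16, 16)
  fw <- patrestore:::networkForward(params, cfg, x, mu, 4, keepCache = TRUE)
  g <- patrestore:::networkBackward(params, cfg, fw$cache,
                                    matrix(rnorm(256), 16, 16))
  walk <- function(p) {
    if (!is.list(p)) return(any(p != 0))
    all(vapply(p, walk, logical(1)))
  }
  expect_true(walk(g))
})

test_that("automated parameter counts equal the closed-form architecture arithmetic", {
  expect_identical(tmtaParameterCount(16), 1456L)
  # doubling the width quadruples the quadratic kernel terms
  expect_identical(tmtaParameterCount(32L) - 27L * 32L,
                   4L * (tmtaParameterCount(16L) - 27L * 16L))
  set.seed(33)
  for (i in 1:10) {
    C <- sample(c(4L, 8L, 12L, 16L), 1)
    cfg <- networkConfig(C, blocks = sample(1:2, 5, replace = TRUE),
                         heads = c(1L, 2L, 4L, 4L, 1L),
                         expansion = runif(1, 1.5, 3),
                         timeDim = sample(c(8L, 16L), 1))
    net <- initNoiseNetwork(cfg, seed = i)
    expect_identical(countParameters(net), closedFormParameterCount(cfg))
  }
})

test_that("a short training run halves the denoising loss on a toy set", {
  cfg <- networkConfig(baseChannels = 8L, heads = c(1L, 2L, 4L, 8L, 1L),
                       timeDim = 16L)
  net <- initNoiseNetwork(cfg, seed = 2)
  sched <- buildSchedule(50L, 50)
  imgs <- makePhantomDataset(16, c("disks", "vessels"), grid = 32L, seed = 5)
  geom <- RingGeometry(nElements = 32L, imageExtent = 6.4)
  pairs <- buildPairedDataset(imgs, geom, "sparse", 8,
                              filt = FilterSpec(band = c(0.5, 10)))
  r <- trainNoiseNetwork(net, pairs, sched, steps = 300L, lr0 = 1e-3,
                         seed = 9, logEvery = 1L)
  first <- mean(head(r$log$loss, 30))
  last <- mean(tail(r$log$loss, 30))
  expect_lt(last, 0.5 * first)
  expect_identical(r$net@step, 300)
})
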