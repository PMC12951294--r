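# one of the 8 symmetries of the square: k %% 4 quarter-turns, transposed
# first when k >= 4
dihedral <- function(m, k) {
  if (k >= 4L) m <- t(m)
  for (i in seq_len(k %% 4L)) m <- t(m)[, rev(seq_len(nrow(m)))]
  m
}

# recursive helpers over parameter/gradient trees (leaves are numeric
# arrays with identical shapes across trees)
treeZero <- function(p) {
  if (is.list(p)) lapply(p, treeZero) else p * 0
}

treeAdd <- function(a, b) {
  if (is.list(a)) mapply(treeAdd, a, b, SIMPLIFY = FALSE) else a + b
}

treeMix <- function(a, b, w) {
  if (is.list(a)) mapply(treeMix, a, b, MoreArgs = list(w = w),
                         SIMPLIFY = FALSE)
  else w * a + (1 - w) * b
}

# one Adam step, updating params / m / v in a single recursive pass.
# Gradient subtrees are matched to parameter subtrees by name (the backward
# pass builds its tree in reverse order).
adamStep <- function(params, grads, m, v, lr, beta1, beta2, eps, step) {
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      if (!is.null(names(p))) g <- g[names(p)]
      out <- mapply(rec, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^step)
    vh <- v / (1 - beta2^step)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  rec(params, grads, m, v)
}

#' Cosine learning-rate decay
#'
#' `lr(step) = lr0 * (1 + cos(pi * step / maxSteps)) / 2`, starting at lr0
#' and decaying to 0 at `maxSteps`.
#'
#' @param step current optimizer step (0-based).
#' @param maxSteps total steps.
#' @param lr0 initial learning rate.
#' @return learning rate
#' @export
cosineLearningRate <- function(step, maxSteps, lr0 = 3e-5) {
  lr0 * (1 + cos(pi * min(step, maxSteps) / maxSteps)) / 2
}

#' Train the noise network
#'
#' Stochastic denoising training: each step samples a mini-batch of
#' (x0, mu) pairs, a state index per pair (uniform on `{1..T}`), a forward
#' state via the closed-form marginal, and minimizes the per-pixel mean
#' squared error between the estimated and generating noise with Adam
#' (beta1 = 0.9, beta2 = 0.99) under cosine learning-rate decay from
#' `lr0` (default 3e-5) to 0. Fully seeded and deterministic.
#'
#' @param net a \linkS4class{NoiseNetwork} (fresh or resumed).
#' @param pairs list of training pairs `list(x0 =, mu =)` (matrices or
#'   \linkS4class{PressureImage}s).
#' @param sched a \linkS4class{DiffusionSchedule}.
#' @param steps optimizer steps to run.
#' @param batchSize images per step (default 2).
#' @param lr0 initial learning rate (default 3e-5).
#' @param beta1,beta2 Adam moment decays (defaults 0.9, 0.99).
#' @param seed seed for batch/noise draws.
#' @param logEvery record the running loss every this many steps.
#' @param emaDecay exponential-moving-average decay for a smoothed copy of
#'   the weights (standard score-model practice for the sampling network);
#'   0 disables it.
#' @param augment apply a random dihedral transform (rotation by a
#'   multiple of 90 degrees, optionally transposed) jointly to each
#'   sampled (x0, mu) pair; square images only.
#' @return list with the trained `net`, a data.frame `log`
#'   (step, loss, lr), and `emaNet` (the EMA weights; equal to `net` when
#'   `emaDecay = 0`)
#' @export
trainNoiseNetwork <- function(net, pairs, sched, steps = 300L,
                              batchSize = 2L, lr0 = 3e-5, beta1 = 0.9,
                              beta2 = 0.99, seed = 1L, logEvery = 25L,
                              emaDecay = 0, augment = FALSE) {
  if (length(pairs) == 0) stop("no training pairs")
  old <- options(matprod = "blas")
  on.exit(options(old), add = TRUE)
  pairs <- lapply(pairs, function(pr) list(
    x0 = if (is(pr$x0, "PressureImage")) pixels(pr$x0) else pr$x0,
    mu = if (is(pr$mu, "PressureImage")) pixels(pr$mu) else pr$mu))
  params <- net@params
  m <- treeZero(params); v <- treeZero(params)
  ema <- if (emaDecay > 0) params else NULL
  logs <- list()
  withSeed(seed, {
    for (s in seq_len(steps)) {
      idx <- sample.int(length(pairs), batchSize, replace = TRUE)
      grads <- NULL
      loss <- 0
      for (i in idx) {
        pr <- pairs[[i]]
        if (augment) {
          k <- sample.int(8L, 1) - 1L
          pr <- list(x0 = dihedral(pr$x0, k), mu = dihedral(pr$mu, k))
        }
        t <- sample.int(sched@nStates, 1)
        fs <- sampleForward(pr$x0, pr$mu, t, sched)
        fw <- networkForward(params, net@config, fs$x, pr$mu, t,
                             keepCache = TRUE)
        resid <- fw$out - fs$eps
        loss <- loss + mean(resid * resid)
        dOut <- 2 * resid / length(resid) / batchSize
        g <- networkBackward(params, net@config, fw$cache, dOut)
        grads <- if (is.null(grads)) g else treeAdd(grads, g)
      }
      loss <- loss / batchSize
      if (!is.finite(loss)) stop("training loss became non-finite at step ", s)
      lr <- cosineLearningRate(s - 1L, steps, lr0)
      upd <- adamStep(params, grads, m, v, lr, beta1, beta2, 1e-8,
                      net@step + s)
      params <- upd$p; m <- upd$m; v <- upd$v
      if (!is.null(ema)) ema <- treeMix(ema, params, emaDecay)
      if (s %% logEvery == 0L || s == 1L || s == steps)
        logs[[length(logs) + 1L]] <- data.frame(step = net@step + s,
                                                loss = loss, lr = lr)
    }
  })
  net@params <- params
  net@step <- net@step + steps
  emaNet <- net
  if (!is.null(ema)) emaNet@params <- ema
  list(net = net, log = do.call(rbind, logs), emaNet = emaNet)
}
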