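# cumulative trapezoid integral on a uniform grid
cumTrapz <- function(y, dt) c(0, cumsum((y[-1] + y[-length(y)]) / 2 * dt))

#' Build a mean-reverting diffusion schedule
#'
#' Discretizes the forward SDE `dx = theta_t (mu - x) dt + sigma_t dw` on a
#' uniform unit-span grid of `T + 1` states with
#' `sigma_t^2 = 2 lambda^2 theta_t` (stationary noise level lambda). The
#' default "cosine" shape ramps theta up as `eps + (1 - cos(pi t)) / 2`
#' (gentle early steps) and is scaled so that the terminal cumulative rate
#' satisfies `exp(-2 thetaBar_T) = 1e-4`, i.e. the terminal marginal has
#' converged to `N(mu, lambda^2)` to within 0.01%. "constant" uses a flat
#' theta scaled to the same terminal value.
#'
#' @param T number of diffusion states (default 200).
#' @param lambda stationary noise level in intensity units (default 50 on
#'   the \[0, 255\] image range).
#' @param kind "cosine" (default) or "constant".
#' @param terminalDecay target for `exp(-2 thetaBar_T)` (default 1e-4).
#' @return a \linkS4class{DiffusionSchedule}
#' @examples
#' sched <- buildSchedule()
#' exp(-2 * sched@thetaBar[nStates(sched) + 1])
#' @export
buildSchedule <- function(T = 200L, lambda = 50,
                          kind = c("cosine", "constant"),
                          terminalDecay = 1e-4) {
  kind <- match.arg(kind)
  if (T < 2L) stop("need at least 2 states")
  if (lambda <= 0) stop("lambda must be positive")
  Tn <- as.integer(T)
  dt <- 1 / Tn
  tg <- seq(0, 1, length.out = Tn + 1L)
  shape <- switch(kind,
    cosine = 0.01 + (1 - cos(pi * tg)) / 2,
    constant = rep(1, Tn + 1L))
  target <- -log(terminalDecay) / 2
  raw <- cumTrapz(shape, dt)
  theta <- shape * (target / raw[Tn + 1L])
  new("DiffusionSchedule", nStates = Tn, lambda = as.numeric(lambda),
      theta = theta, sigma = sqrt(2 * lambda^2 * theta),
      thetaBar = cumTrapz(theta, dt), dt = dt, kind = kind)
}

#' @rdname DiffusionSchedule-class
#' @param object,x a \linkS4class{DiffusionSchedule}
#' @export
setMethod("nStates", "DiffusionSchedule", function(x) x@nStates)

#' @rdname DiffusionSchedule-class
#' @export
setMethod("noiseLevel", "DiffusionSchedule", function(x) x@lambda)

setMethod("show", "DiffusionSchedule", function(object) {
  Tn <- object@nStates
  cat(sprintf(
    "DiffusionSchedule: %d states, lambda = %g, %s theta ramp\n",
    Tn, object@lambda, object@kind))
  cat(sprintf("  terminal exp(-2 thetaBar_T) = %.3g\n",
              exp(-2 * object@thetaBar[Tn + 1])))
})

checkState <- function(sched, t) {
  if (t < 0 || t > sched@nStates)
    stop("state index must lie in [0, ", sched@nStates, "]")
}

#' Closed-form marginal parameters of the forward SDE
#'
#' The state at time t is Gaussian with mean
#' `m_t = mu + (x0 - mu) exp(-thetaBar_t)` and variance
#' `v_t = lambda^2 (1 - exp(-2 thetaBar_t))`: the clean image decays toward
#' the degraded image while noise builds up to the stationary level.
#'
#' @param x0 clean image (matrix or \linkS4class{PressureImage}).
#' @param mu degraded image, same shape.
#' @param t state index in \[0, T\].
#' @param sched a \linkS4class{DiffusionSchedule}.
#' @return list with `m` (same shape as x0) and scalar `v`
#' @examples
#' sched <- buildSchedule(T = 10L, lambda = 50)
#' marginalParams(0, 100, 10, sched)
#' @export
marginalParams <- function(x0, mu, t, sched) {
  if (is(x0, "PressureImage")) x0 <- pixels(x0)
  if (is(mu, "PressureImage")) mu <- pixels(mu)
  if (!identical(dim(x0), dim(mu)) && !(length(x0) == length(mu)))
    stop("x0 and mu must have the same shape")
  checkState(sched, t)
  tb <- sched@thetaBar[t + 1]
  list(m = mu + (x0 - mu) * exp(-tb),
       v = sched@lambda^2 * (1 - exp(-2 * tb)))
}

#' Sample the forward diffusion at one state
#'
#' Reparameterized draw `x_t = m_t + sqrt(v_t) * eps` with eps standard
#' Gaussian; returns both the state and the generating noise (the network's
#' regression target).
#'
#' @inheritParams marginalParams
#' @return list with `x` (the state), `eps`, `m`, `v`, and `t`
#' @export
sampleForward <- function(x0, mu, t, sched) {
  if (is(x0, "PressureImage")) x0 <- pixels(x0)
  if (is(mu, "PressureImage")) mu <- pixels(mu)
  mp <- marginalParams(x0, mu, t, sched)
  eps <- array(stats::rnorm(length(x0)), dim = dim(as.array(x0)))
  if (is.null(dim(x0))) eps <- as.numeric(eps)
  list(x = mp$m + sqrt(mp$v) * eps, eps = eps, m = mp$m, v = mp$v, t = t)
}

#' Score from the noise reparameterization
#'
#' Under `x_t = m_t + sqrt(v_t) eps`, the score of the Gaussian marginal is
#' `grad_x log p_t(x) = -(x_t - m_t) / v_t = -eps / sqrt(v_t)`.
#'
#' @param eps the standard Gaussian draw (or the network's estimate).
#' @param v marginal variance v_t, must be positive.
#' @return score field, same shape as eps
#' @export
scoreFromNoise <- function(eps, v) {
  if (v <= 0) stop("score undefined at zero variance (t = 0)")
  -eps / sqrt(v)
}

#' Analytic score of the forward marginal
#'
#' `-(x - m_t) / v_t`, available when the clean image is known; used as the
#' exact-score oracle for the reverse sampler.
#'
#' @param x current state.
#' @inheritParams marginalParams
#' @return score field
#' @export
analyticScore <- function(x, x0, mu, t, sched) {
  mp <- marginalParams(x0, mu, t, sched)
  if (mp$v <= 0) stop("score undefined at zero variance (t = 0)")
  -(x - mp$m) / mp$v
}

#' Training loss of the noise network
#'
#' Monte-Carlo estimate of the denoising objective: for each pair a state
#' index is drawn uniformly from `{1, ..., T}`, the forward marginal is
#' sampled, and the per-pixel mean squared error between the network's
#' noise estimate and the generating noise is recorded. Returns the mean
#' over the batch.
#'
#' @param net a \linkS4class{NoiseNetwork}, or a function
#'   `(x, mu, t) -> eps-hat` (used by oracle tests).
#' @param batch list of `(x0, mu)` pairs as produced by
#'   [makeTrainingPair()] (matrices or \linkS4class{PressureImage}s).
#' @param sched a \linkS4class{DiffusionSchedule}.
#' @return scalar loss
#' @export
trainingLoss <- function(net, batch, sched) {
  if (length(batch) == 0) stop("batch must be non-empty")
  fwd <- if (is.function(net)) net else
    function(x, mu, t) predictNoise(net, x, mu, t)
  losses <- vapply(batch, function(pair) {
    x0 <- if (is(pair$x0, "PressureImage")) pixels(pair$x0) else pair$x0
    mu <- if (is(pair$mu, "PressureImage")) pixels(pair$mu) else pair$mu
    if (!identical(dim(x0), dim(mu))) stop("pair shapes differ")
    t <- sample.int(sched@nStates, 1)
    fs <- sampleForward(x0, mu, t, sched)
    mean((fwd(fs$x, mu, t) - fs$eps)^2)
  }, numeric(1))
  mean(losses)
}

#' Restore an image by reverse-time diffusion
#'
#' Initializes at the terminal marginal `x_T ~ N(mu, v_T)` and integrates
#' backward to state 0. Two discretizations are provided:
#'
#' `method = "em"` (default) is an Euler--Maruyama scheme on the
#' reverse-time SDE
#' `dx = [theta_t (mu - x) - sigma_t^2 score] dt + sigma_t d w-hat`,
#' substituting `score = -eps-hat / sqrt(v_t)` with the network's noise
#' estimate (or an exact score function for oracle runs). No noise is added
#' at the final step.
#'
#' `method = "posterior"` is the exact reverse path of the mean-reverting
#' process: at each step the noise estimate is converted into a clean-image
#' estimate `x0-hat = mu + (x_t - sqrt(v_t) eps-hat - mu) exp(thetaBar_t)`
#' (clipped into `clipRange`, which keeps the iteration stable when the
#' estimate is imperfect), and the state is moved to the Gaussian posterior
#' of the earlier state given the current one and x0-hat. With
#' `stochastic = FALSE` the posterior mean is followed (a deterministic
#' restoration path, the package default for trained networks).
#'
#' The output is clipped to `clipRange` at the end only.
#'
#' @param mu degraded image (matrix or \linkS4class{PressureImage}).
#' @param net a \linkS4class{NoiseNetwork}, or a function
#'   `(x, t) -> score` when `scoreFn = TRUE`.
#' @param sched a \linkS4class{DiffusionSchedule}.
#' @param steps number of reverse steps (default T; fewer steps stride the
#'   state grid uniformly).
#' @param scoreFn set TRUE if `net` is already a score function `(x, t)`
#'   (only supported with `method = "em"`).
#' @param method "em" or "posterior" (see Details).
#' @param stochastic inject the reverse noise (TRUE for the SDE path;
#'   FALSE follows the posterior mean, `method = "posterior"` only).
#' @param clipRange dynamic range used for the final clip and for the
#'   posterior method's x0-hat projection, or NULL to skip both.
#' @return restored image, same shape as `mu` (matrix)
#' @export
reverseSample <- function(mu, net, sched, steps = nStates(sched),
                          scoreFn = FALSE,
                          method = c("em", "posterior"),
                          stochastic = TRUE, clipRange = c(0, 255)) {
  method <- match.arg(method)
  if (is(mu, "PressureImage")) mu <- pixels(mu)
  Tn <- sched@nStates
  if (steps < 1 || steps > Tn) stop("steps must lie in [1, T]")
  if (scoreFn && method == "posterior")
    stop("the posterior method needs a noise network, not a score function")
  old <- options(matprod = "blas")
  on.exit(options(old), add = TRUE)
  grid <- unique(round(seq(0, Tn, length.out = steps + 1)))
  lam2 <- sched@lambda^2
  tb <- sched@thetaBar
  vOf <- function(t) lam2 * (1 - exp(-2 * tb[t + 1]))
  noise <- function() array(stats::rnorm(length(mu)),
                            dim = dim(as.array(mu)))
  x <- mu + sqrt(vOf(Tn)) * noise()
  if (is.null(dim(mu))) x <- as.numeric(x)
  if (method == "em") {
    score <- if (scoreFn) net else function(x, t)
      scoreFromNoise(predictNoise(net, x, mu, t), vOf(t))
    for (k in seq(length(grid) - 1, 1)) {
      t1 <- grid[k + 1]; t0 <- grid[k]
      dtk <- (t1 - t0) * sched@dt
      th <- sched@theta[t1 + 1]; sg <- sched@sigma[t1 + 1]
      drift <- th * (mu - x) - sg^2 * score(x, t1)
      x <- x - drift * dtk
      if (k > 1 && stochastic) x <- x + sg * sqrt(dtk) * noise()
      if (any(!is.finite(x)))
        stop("reverse diffusion diverged at state ", t0)
    }
  } else {
    for (k in seq(length(grid) - 1, 1)) {
      t1 <- grid[k + 1]; t0 <- grid[k]
      vt <- vOf(t1); vs <- vOf(t0)
      eh <- predictNoise(net, x, mu, t1)
      x0h <- mu + (x - sqrt(vt) * eh - mu) * exp(tb[t1 + 1])
      if (!is.null(clipRange)) x0h <- clip(x0h, clipRange[1], clipRange[2])
      dtb <- tb[t1 + 1] - tb[t0 + 1]
      mS <- mu + (x0h - mu) * exp(-tb[t0 + 1])
      mT <- mu + (x0h - mu) * exp(-tb[t1 + 1])
      gain <- (vs / vt) * exp(-dtb)
      x <- mS + gain * (x - mT)
      if (k > 1 && stochastic) {
        vp <- vs * (1 - vs * exp(-2 * dtb) / vt)
        x <- x + sqrt(max(vp, 0)) * noise()
      }
      if (any(!is.finite(x)))
        stop("reverse diffusion diverged at state ", t0)
    }
  }
  if (!is.null(clipRange)) x <- clip(x, clipRange[1], clipRange[2])
  x
}
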