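test_that("schedules satisfy the volatility constraint and terminal convergence", {
  for (kind in c("cosine", "constant")) {
    s <- buildSchedule(200L, 50, kind)
    expect_identical(nStates(s), 200L)
    expect_identical(noiseLevel(s), 50)
    expect_lt(max(abs(s@sigma^2 / s@theta - 2 * 50^2)), 1e-9)
    expect_true(all(diff(s@thetaBar) > 0))
    expect_lte(exp(-2 * s@thetaBar[201]), 1e-4 + 1e-12)
  }
  expect_error(buildSchedule(1L, 50), "2 states")
  expect_error(buildSchedule(200L, 0), "lambda")
})

test_that("marginals interpolate from the clean image to the degraded prior", {
  sched <- buildSchedule(100L, 50)
  x0 <- matrix(10, 8, 8); mu <- matrix(200, 8, 8)
  m0 <- marginalParams(x0, mu, 0, sched)
  expect_identical(m0$m, x0)
  expect_identical(m0$v, 0)
  mT <- marginalParams(x0, mu, 100, sched)
  # terminal decay e^(-thetaBar_T) = 0.01 by construction
  expect_lte(max(abs(mT$m - mu)), 0.0101 * max(abs(x0 - mu)))
  expect_equal(mT$v, 50^2 * (1 - 1e-4), tolerance = 1e-9)
  expect_error(marginalParams(x0, mu, 101, sched), "state index")
})

test_that("closed-form marginals match an Euler-Maruyama integration of the SDE", {
  # constant theta = 1 on a unit time span (terminal decay e^-2), checked
  # at t = 0.5 against 1e5 simulated paths
  sched <- buildSchedule(500L, 50, "constant", terminalDecay = exp(-2))
  expect_equal(sched@theta[1], 1, tolerance = 1e-12)
  mp <- marginalParams(0, 100, 250L, sched)
  expect_equal(mp$m, 100 * (1 - exp(-0.5)), tolerance = 1e-9)
  expect_equal(mp$v, 2500 * (1 - exp(-1)), tolerance = 1e-9)

  nPaths <- 1e5
  dt <- 1 / 500
  set.seed(41)
  x <- numeric(nPaths)
  for (i in 1:250) {
    x <- x + 1 * (100 - x) * dt +
      sqrt(2 * 2500) * sqrt(dt) * rnorm(nPaths)
  }
  seMean <- sd(x) / sqrt(nPaths)
  expect_lt(abs(mean(x) - mp$m), 3 * seMean + 0.15)   # + Euler bias margin
  seVar <- var(x) * sqrt(2 / (nPaths - 1))
  expect_lt(abs(var(x) - mp$v), 3 * seVar + 0.01 * mp$v)
})

test_that("forward samples are reproducible and obey the marginal law", {
  sched <- buildSchedule(100L, 50)
  x0 <- matrix(c(1:32, 32:1) + 0, 8, 8); mu <- 255 - x0
  s0 <- sampleForward(x0, mu, 0, sched)
  expect_identical(s0$x, x0)

  set.seed(5); a <- sampleForward(x0, mu, 30, sched)
  set.seed(5); b <- sampleForward(x0, mu, 30, sched)
  expect_identical(a$x, b$x)
  expect_identical(a$eps, b$eps)

  n <- 1e5
  mp <- marginalParams(3, 150, 50, sched)
  set.seed(7)
  big <- sampleForward(rep(3, n), rep(150, n), 50, sched)$x
  expect_lt(abs(mean(big) - mp$m), 4 * sqrt(mp$v / n))
  expect_lt(abs(var(big) - mp$v), 4 * mp$v * sqrt(2 / (n - 1)))

  # the empirical law matches the closed form on a grid across the span
  set.seed(8)
  for (t in round(seq(10, 100, length.out = 10))) {
    m <- 1e4
    d <- sampleForward(rep(40, m), rep(210, m), t, sched)$x
    mp <- marginalParams(40, 210, t, sched)
    expect_lt(abs(mean(d) - mp$m), 4 * sqrt(mp$v / m))
    expect_lt(abs(var(d) - mp$v), 4 * mp$v * sqrt(2 / (m - 1)))
  }
})

test_that("the noise reparameterization reproduces the Gaussian score", {
  expect_identical(scoreFromNoise(matrix(0, 4, 4), 25), matrix(0, 4, 4))
  eps <- matrix(rnorm(16), 4, 4)
  expect_equal(scoreFromNoise(-eps, 25), -scoreFromNoise(eps, 25))
  expect_error(scoreFromNoise(eps, 0), "zero variance")

  # identity between the two score forms on generated states
  sched <- buildSchedule(100L, 50)
  set.seed(8)
  fs <- sampleForward(matrix(20, 6, 6), matrix(180, 6, 6), 40, sched)
  expect_equal(scoreFromNoise(fs$eps, fs$v),
               analyticScore(fs$x, matrix(20, 6, 6), matrix(180, 6, 6), 40,
                             sched),
               tolerance = 1e-12)

  # finite differences of the log marginal density (exact for a quadratic)
  set.seed(9)
  for (i in 1:100) {
    m <- runif(1, 0, 255); v <- runif(1, 1, 2500); x <- rnorm(1, m, sqrt(v))
    h <- 1e-3 * sqrt(v)
    fd <- (dnorm(x + h, m, sqrt(v), log = TRUE) -
             dnorm(x - h, m, sqrt(v), log = TRUE)) / (2 * h)
    sc <- scoreFromNoise((x - m) / sqrt(v), v)
    expect_lt(abs(sc - fd) / max(abs(fd), 1e-8), 1e-5)
  }
})

test_that("the training loss is zero for an oracle and ~1 for a silent network", {
  sched <- buildSchedule(50L, 50)
  x0 <- matrix(runif(64, 0, 255), 8, 8); mu <- matrix(runif(64, 0, 255), 8, 8)
  batch <- replicate(30, list(x0 = x0, mu = mu), simplify = FALSE)

  oracle <- function(x, m, t) {
    mp <- marginalParams(x0, m, t, sched)
    (x - mp$m) / sqrt(mp$v)
  }
  set.seed(10)
  expect_lt(trainingLoss(oracle, batch, sched), 1e-20)

  silent <- function(x, m, t) x * 0
  set.seed(10)
  loss <- trainingLoss(silent, batch, sched)
  se <- sqrt(2 / (64 * 30))
  expect_lt(abs(loss - 1), 4 * se)
  expect_error(trainingLoss(silent, list(), sched), "non-empty")
})

test_that("the reverse sampler inverts the degradation given the exact score", {
  # near-deterministic regime: tiny lambda makes the reverse SDE an ODE
  # whose solution is the marginal mean path, ending at x0
  sched <- buildSchedule(200L, 1e-6)
  x0 <- matrix(200, 8, 8); mu <- matrix(50, 8, 8)
  sc <- function(x, t) analyticScore(x, x0, mu, t, sched)
  set.seed(11)
  out <- reverseSample(mu, sc, sched, scoreFn = TRUE)
  expect_lt(max(abs(out - x0)) / 200, 1e-3)

  # determinism of the stochastic sampler
  sched50 <- buildSchedule(100L, 50)
  sc50 <- function(x, t) analyticScore(x, x0, mu, t, sched50)
  set.seed(12); r1 <- reverseSample(mu, sc50, sched50, scoreFn = TRUE)
  set.seed(12); r2 <- reverseSample(mu, sc50, sched50, scoreFn = TRUE)
  expect_identical(r1, r2)
})

test_that("exact-score recovery improves as the reverse grid is refined", {
  sched <- buildSchedule(200L, 50)
  x0 <- matrix(180, 8, 8); mu <- matrix(60, 8, 8)
  sc <- function(x, t) analyticScore(x, x0, mu, t, sched)
  err <- vapply(c(25L, 50L, 100L, 200L), function(st) {
    set.seed(13)
    mean(vapply(1:40, function(i)
      mean(abs(reverseSample(mu, sc, sched, steps = st, scoreFn = TRUE) -
                 x0)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("a diverging state is reported with its step", {
  sched <- buildSchedule(50L, 50)
  bad <- function(x, t) x * NA_real_
  set.seed(14)
  expect_error(reverseSample(matrix(0, 8, 8), bad, sched, scoreFn = TRUE),
               "diverged")
})
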