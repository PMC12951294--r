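test_that("the band-pass window passes the mid-band and rejects band edges", {
  spec <- FilterSpec()
  expect_gte(filterResponse(spec, 2), 0.99 * max(filterResponse(
    spec, seq(0.1, 20, by = 0.01))))
  # each band edge is the -3 dB point of its own Butterworth factor
  expect_equal(filterResponse(spec, 0.5), 1 / sqrt(2), tolerance = 1e-3)
  expect_equal(filterResponse(spec, 10), 1 / sqrt(2), tolerance = 1e-3)
  expect_error(FilterSpec(band = c(5, 2)), "low < high")
})

test_that("the back-projection term combines the filtered trace and its ramp derivative", {
  geom <- RingGeometry(nElements = 2L, nSamples = 2048L)
  dt <- 1 / 62.5
  tt <- (0:2047) * dt
  f <- round(3 * 2048 * dt) / (2048 * dt)   # in-band, exactly on the grid
  s <- sin(2 * pi * f * tt)
  sino <- Sinogram(rbind(s, s), geom)
  b <- backprojectionTerm(sino)
  analytic <- 2 * s - tt * (2 * pi * f) * cos(2 * pi * f * tt)
  interior <- 100:1900
  expect_lt(relL2(b[1, interior], analytic[interior]), 0.03)

  zero <- Sinogram(matrix(0, 2, 2048), geom)
  expect_true(all(backprojectionTerm(zero) == 0))
  expect_error(backprojectionTerm(sino, FilterSpec(band = c(0.5, 40))),
               "Nyquist")
})

test_that("the universal back-projection variant is available via derivativeWeight", {
  # b is affine in the derivative weight w: b_w = 2*smoothed - w*t*deriv,
  # so w = 0, 1, 2 must be collinear and w = 0 must drop the ramp term
  sino <- fixtureSinogram()
  b0 <- backprojectionTerm(sino, FilterSpec(derivativeWeight = 0))
  b1 <- backprojectionTerm(sino, FilterSpec(derivativeWeight = 1))
  b2 <- backprojectionTerm(sino, FilterSpec(derivativeWeight = 2))
  expect_false(isTRUE(all.equal(b1, b2)))
  expect_equal(b2, 2 * b1 - b0, tolerance = 1e-9)
  # the w = 0 term is twice the band-passed trace (check one trace by fft)
  tr <- traces(sino)[3, ]
  nt <- length(tr)
  f <- patrestore:::fftFreqs(nt, sino@dt)
  W <- filterResponse(FilterSpec(), abs(f))
  sm <- Re(stats::fft(W * stats::fft(tr), inverse = TRUE)) / nt
  expect_equal(b0[3, ], 2 * sm, tolerance = 1e-9)
})

test_that("zero sinograms reconstruct to zero and off-grid arrivals error", {
  geom <- fixtureGeom(8L)
  zero <- Sinogram(matrix(0, 8, geom@nSamples), geom)
  rec <- fbpReconstruct(zero, ReconGrid(16L, 3.2))
  expect_true(all(pixels(rec) == 0))

  shortGeom <- RingGeometry(nElements = 8L, nSamples = 1000L)
  shortSino <- Sinogram(matrix(0, 8, 1000L), shortGeom)
  expect_error(fbpReconstruct(shortSino, ReconGrid(16L, 3.2)), "window")
  expect_error(fbpReconstruct(zero, ReconGrid(16L, 90)), "inside")
})

test_that("a reconstructed disk lands at its true position", {
  sp <- 0.15
  co <- gridCoords(64, 64, sp)
  disk <- matrix(as.numeric((co[, 1] - 1.2)^2 + (co[, 2] + 0.9)^2 <=
                              (3 * sp)^2), 64, 64)
  geom <- RingGeometry(nElements = 128L, imageExtent = 64 * sp)
  rec <- fbpReconstruct(simulateSignals(PressureImage(disk, spacing = sp),
                                        geom), ReconGrid(64L, 64 * sp))
  cen <- featureCentroid(rec)
  expect_lt(sqrt(sum((cen - c(1.2, -0.9))^2)), sp)
})

test_that("reconstruction degrades monotonically from 256 to 32 sparse views", {
  sino <- fixtureSinogram()
  grid <- ReconGrid(48L, 9.6)
  full <- fbpReconstruct(sino, grid)
  p32 <- psnr(pixels(full),
              pixels(fbpReconstruct(subsampleViews(sino, "sparse", 8), grid)),
              dataRange = diff(range(pixels(full))))
  p256 <- psnr(pixels(full),
               pixels(fbpReconstruct(subsampleViews(sino, "sparse", 32),
                                     grid)),
               dataRange = diff(range(pixels(full))))
  expect_lt(p32, p256)
})

test_that("training pairs share the full-view normalization", {
  img <- fixturePhantom()
  geom <- fixtureGeom(64L)
  pair <- makeTrainingPair(img, geom, "sparse", 8, ReconGrid(48L, 9.6),
                           sino = fixtureSinogram())
  expect_identical(range(pixels(pair$x0)), c(0, 255))
  expect_true(all(pixels(pair$mu) >= 0 & pixels(pair$mu) <= 255))
  p <- psnr(pair$x0, pair$mu)
  expect_true(is.finite(p))

  ident <- makeTrainingPair(img, geom, "sparse", 64, ReconGrid(48L, 9.6),
                            sino = fixtureSinogram())
  expect_identical(pixels(ident$x0), pixels(ident$mu))

  lim <- subsampleViews(fixtureSinogram(), "limited", pi)
  expect_identical(nrow(traces(lim)), 32L)  # half the 64-element ring
})
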