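test_that("detector positions are arc-uniform on the stated circle", {
  pos <- detectorPositions(RingGeometry(nElements = 4L))
  expect_equal(pos, cbind(x = c(40, 0, -40, 0), y = c(0, 40, 0, -40)),
               tolerance = 1e-12, ignore_attr = TRUE)

  geomArc <- RingGeometry(nElements = 128L, coverage = pi / 2)
  posArc <- detectorPositions(geomArc)
  ang <- atan2(posArc[, 2], posArc[, 1])
  expect_true(all(ang >= -1e-12 & ang <= pi / 2))
  expect_equal(diff(ang), rep(pi / 2 / 128, 127), tolerance = 1e-9)

  expect_true(all(abs(sqrt(rowSums(posArc^2)) - 40) < 1e-9))
})

test_that("the forward model is linear and a zero image maps to zero signal", {
  geom <- fixtureGeom(8L)
  zero <- PressureImage(matrix(0, 48, 48), spacing = 0.2)
  expect_true(all(traces(simulateSignals(zero, geom)) == 0))

  i1 <- generatePhantom(PhantomSpec("disks", seed = 1L), 48, spacing = 0.2)
  i2 <- generatePhantom(PhantomSpec("vessels", seed = 2L), 48, spacing = 0.2)
  comb <- PressureImage(2 * pixels(i1) - 0.5 * pixels(i2), spacing = 0.2)
  tc <- traces(simulateSignals(comb, geom))
  tlin <- 2 * traces(simulateSignals(i1, geom)) -
    0.5 * traces(simulateSignals(i2, geom))
  expect_lt(relL2(tc, tlin), 1e-10)
})

test_that("a centered radially symmetric phantom gives identical traces", {
  # 4 detectors on the axes see the pixel grid symmetrically, so traces
  # agree to floating-point accuracy
  co <- gridCoords(49, 49, 0.2)
  blob <- matrix(exp(-(co[, 1]^2 + co[, 2]^2) / (2 * 0.6^2)), 49, 49)
  sino <- simulateSignals(PressureImage(blob, spacing = 0.2),
                          RingGeometry(nElements = 4L, imageExtent = 9.8))
  tr <- traces(sino)
  for (d in 2:4)
    expect_lt(relL2(tr[d, ], tr[1, ]), 1e-6)
})

test_that("a point source at the ring center arrives at t = radius / v", {
  p <- matrix(0, 49, 49); p[25, 25] <- 1   # odd grid: center pixel at (0,0)
  geom <- RingGeometry(nElements = 8L, imageExtent = 9.8)
  tr <- traces(simulateSignals(PressureImage(p, spacing = 0.2), geom))
  # 40 mm at 1.5 mm/us sampled at 62.5 MHz -> sample index ~ 1667
  expected <- 40 / 1.5 * 62.5
  peak <- which.max(abs(tr[1, ]))
  expect_lt(abs(peak - expected), 4)
  # signal energy is concentrated near the arrival
  win <- abs(seq_len(ncol(tr)) - expected) <= 10
  expect_gt(sum(tr[1, win]^2), 0.99 * sum(tr[1, ]^2))
})

test_that("rotating the phantom by one detector pitch permutes the traces", {
  img <- pixels(fixturePhantom())
  rot90 <- t(img)[, rev(seq_len(nrow(img)))]  # 90-degree rotation
  geom <- RingGeometry(nElements = 4L, imageExtent = 9.6)
  tr <- traces(simulateSignals(PressureImage(img, spacing = 0.2), geom))
  trR <- traces(simulateSignals(PressureImage(rot90, spacing = 0.2), geom))
  perm <- tr[c(4, 1, 2, 3), ]
  expect_lt(relL2(trR, perm), 1e-6)
})

test_that("the vectorized projector matches the brute-force oracle", {
  img <- generatePhantom(PhantomSpec("disks", seed = 4L), 32, spacing = 0.25)
  geom <- RingGeometry(nElements = 6L, imageExtent = 8)
  tr <- traces(simulateSignals(img, geom))
  det <- detectorPositions(geom)
  for (d in c(1L, 4L)) {
    oracle <- bruteForceTrace(img, det[d, ], 1.5, 1 / 62.5, geom@nSamples)
    expect_lt(relL2(tr[d, ], oracle), 0.02)
  }
})

test_that("images that do not fit the geometry are rejected", {
  big <- PressureImage(matrix(1, 500, 500), spacing = 0.2)  # 100 mm wide
  expect_error(simulateSignals(big, fixtureGeom(8L)), "outside")
  short <- RingGeometry(nElements = 4L, nSamples = 100L)
  small <- PressureImage(matrix(1, 16, 16), spacing = 0.2)
  expect_error(simulateSignals(small, short), "truncated")
})

test_that("sparse and limited subsampling keep the stated detector subsets", {
  sino <- fixtureSinogram()  # 64-element full ring
  full <- subsampleViews(sino, "sparse", 64)
  expect_true(all(detectorMask(full)))
  expect_identical(traces(full), traces(sino))

  sp8 <- subsampleViews(sino, "sparse", 8)
  expect_identical(which(detectorMask(sp8)), seq(1L, 64L, by = 8L))
  expect_identical(traces(sp8), traces(sino)[seq(1, 64, by = 8), ])

  lim <- subsampleViews(sino, "limited", pi / 2)
  expect_identical(which(detectorMask(lim)), 1:16)
  expect_identical(traces(lim), traces(sino)[1:16, ])

  expect_error(subsampleViews(sino, "sparse", 7), "divide")
  expect_error(subsampleViews(sino, "limited", 3 * pi), "coverage")
})
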