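# shared small fixtures, built once per test run

# 48 x 48 disk phantom on a 9.6 mm grid, 64-element full ring
fixtureGeom <- function(nElements = 64L) {
  RingGeometry(nElements = nElements, imageExtent = 9.6)
}

fixturePhantom <- local({
  img <- NULL
  function() {
    if (is.null(img))
      img <<- generatePhantom(
        PhantomSpec("disks", countRange = c(2, 4), radiusRange = c(0.4, 1),
                    seed = 7L), grid = 48L, spacing = 0.2)
    img
  }
})

fixtureSinogram <- local({
  sino <- NULL
  function() {
    if (is.null(sino)) sino <<- simulateSignals(fixturePhantom(),
                                                fixtureGeom())
    sino
  }
})

# brute-force forward projector used as the independent oracle: per-pixel
# accumulation into distance bins, plain R loops, optionally on a finer grid
bruteForceTrace <- function(img, detXY, vmmus, dt, nt, refine = 1L) {
  p <- pixels(img)
  sp <- spacing(img) / refine
  if (refine > 1L) {
    p <- p[rep(seq_len(nrow(p)), each = refine),
           rep(seq_len(ncol(p)), each = refine)] / refine^2
  }
  H <- nrow(p); W <- ncol(p)
  x <- (rep(seq_len(W), each = H) - (W + 1) / 2) * sp
  y <- (rep(seq_len(H), times = W) - (H + 1) / 2) * sp
  dr <- vmmus * dt
  g <- numeric(nt)
  v <- as.numeric(p)
  for (i in seq_along(v)) {
    if (v[i] == 0) next
    b <- floor(sqrt((x[i] - detXY[1])^2 + (y[i] - detXY[2])^2) / dr) + 1
    if (b <= nt) g[b] <- g[b] + v[i]
  }
  g <- g * sp^2 / dr / (2 * pi * ((seq_len(nt) - 0.5) * dr))
  tr <- numeric(nt)
  tr[2:(nt - 1)] <- (g[3:nt] - g[1:(nt - 2)]) / (2 * dt)
  tr
}

relL2 <- function(a, b) sqrt(sum((a - b)^2) / max(sum(b^2), 1e-300))

expect_rel_equal <- function(a, b, tol) {
  expect_lt(max(abs(a - b)) / max(max(abs(b)), 1e-12), tol)
}
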