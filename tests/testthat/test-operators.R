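# Periodic differential operators, Poisson solver and torus centroid.

test_that("gradient is exact on analytic modes and zero on constants", {
  g <- makeGrid(32, 48)
  co <- gridCoords(g)
  for (scheme in c("spectral", "fd")) {
    gr <- fieldGradient(matrix(3.7, g$nx, g$ny), g, scheme)
    expect_equal(max(abs(gr$x)), 0)
    expect_equal(max(abs(gr$y)), 0)

    f <- sin(2 * pi * co$X / g$Lx)
    gr <- fieldGradient(f, g, scheme)
    exact <- (2 * pi / g$Lx) * cos(2 * pi * co$X / g$Lx)
    tol <- if (scheme == "spectral") 1e-12 else 10 * g$dx^2 * (2 * pi / g$Lx)^3
    expect_lt(max(abs(gr$x - exact)), max(tol, 1e-12))
    expect_lt(max(abs(gr$y)), 1e-12)
    # periodic consistency: both components have exactly zero mean
    r <- bandLimitedField(g, 6, seed = 3)
    grr <- fieldGradient(r, g, scheme)
    expect_lt(abs(mean(grr$x)), 1e-14)
    expect_lt(abs(mean(grr$y)), 1e-14)
  }
})

test_that("fd gradient of a random periodic field agrees with the spectral oracle", {
  g <- makeGrid(64, 64)
  f <- bandLimitedField(g, 5, seed = 11, amp = 1)
  gfd <- fieldGradient(f, g, "fd")
  gsp <- fieldGradient(f, g, "spectral") # exact for band-limited fields
  expect_lt(max(abs(gfd$x - gsp$x)), 10 * g$dx^2)
  expect_lt(max(abs(gfd$y - gsp$y)), 10 * g$dy^2)
})

test_that("non-finite input is rejected", {
  g <- makeGrid(16, 16)
  f <- matrix(0, 16, 16); f[3, 4] <- NaN
  expect_error(fieldGradient(f, g), "non-finite")
  expect_error(fieldLaplacian(f, g), "non-finite")
})

test_that("curl of a gradient vanishes and the Laplacian has Fourier eigenfunctions", {
  g <- makeGrid(48, 32)
  co <- gridCoords(g)
  for (scheme in c("spectral", "fd")) {
    f <- bandLimitedField(g, 5, seed = 4)
    curl <- fieldCurl2d(fieldGradient(f, g, scheme), g, scheme)
    expect_lt(max(abs(curl)), 1e-12)

    k <- 2 * pi / g$Lx
    f <- sin(k * co$X)
    lap <- fieldLaplacian(f, g, scheme)
    lam <- if (scheme == "spectral") -k^2 else (2 * cos(k * g$dx) - 2) / g$dx^2
    expect_equal(lap, lam * f, tolerance = 1e-10)
  }
})

test_that("operators are translation-equivariant on the torus", {
  g <- makeGrid(32, 32)
  f <- bandLimitedField(g, 6, seed = 9, amp = 1)
  for (scheme in c("spectral", "fd")) {
    gr <- fieldGradient(f, g, scheme)
    grs <- fieldGradient(rollMatrix(f, 5, -3), g, scheme)
    expect_equal(grs$x, rollMatrix(gr$x, 5, -3), tolerance = 1e-12)
    expect_equal(grs$y, rollMatrix(gr$y, 5, -3), tolerance = 1e-12)
    lp <- fieldLaplacian(f, g, scheme)
    expect_equal(fieldLaplacian(rollMatrix(f, 5, -3), g, scheme),
                 rollMatrix(lp, 5, -3), tolerance = 1e-12)
  }
})

test_that("Poisson solve inverts the Laplacian on zero-mean fields", {
  g <- makeGrid(64, 64)
  co <- gridCoords(g)
  for (scheme in c("spectral", "fd")) {
    # rhs = 0 -> psi = 0
    expect_equal(solvePoisson(matrix(0, 64, 64), g, scheme),
                 matrix(0, 64, 64))
    # single mode: rhs = -k^2 sin(kx) -> psi = sin(kx) (spectral exact)
    k <- 2 * pi / g$Lx
    s <- sin(k * co$X)
    if (scheme == "spectral") {
      expect_equal(solvePoisson(-k^2 * s, g, scheme), s, tolerance = 1e-10)
    } else {
      lamk <- (2 * cos(k * g$dx) - 2) / g$dx^2
      expect_equal(solvePoisson(lamk * s, g, scheme), s, tolerance = 1e-10)
    }
    # random zero-mean rhs: residual below tolerance; zero-mean gauge
    r <- bandLimitedField(g, 7, seed = 21, amp = 1)
    r <- r - mean(r)
    psi <- solvePoisson(r, g, scheme)
    expect_lt(abs(mean(psi)), 1e-12)
    expect_lt(max(abs(fieldLaplacian(psi, g, scheme) - r)), 1e-8)
  }
  # solvability: non-zero-mean rhs rejected
  expect_error(solvePoisson(matrix(1, 64, 64), g), "zero spatial mean")
})

test_that("stream-function velocity is exactly divergence-free", {
  g <- makeGrid(48, 48)
  co <- gridCoords(g)
  # psi constant -> v = 0
  v0 <- velocityFromStream(matrix(2, 48, 48), g, "fd")
  expect_equal(max(abs(v0$x), abs(v0$y)), 0)
  # psi = sin(2 pi y / Ly) -> v = ((2 pi/Ly) cos(...), 0)
  k <- 2 * pi / g$Ly
  v <- velocityFromStream(sin(k * co$Y), g, "spectral")
  expect_equal(v$x, k * cos(k * co$Y), tolerance = 1e-10)
  expect_lt(max(abs(v$y)), 1e-12)
  # arbitrary psi: divergence at rounding level (fd) / spectral tolerance
  psi <- matrix(rnorm(48 * 48), 48, 48)
  for (scheme in c("fd", "spectral")) {
    v <- velocityFromStream(psi, g, scheme)
    tol <- if (scheme == "fd") 1e-12 else 1e-8
    expect_lt(max(abs(fieldDivergence(v, g, scheme))), tol)
  }
})

test_that("torus centroid handles interior, translated and straddling droplets", {
  g <- makeGrid(64, 64)
  co <- gridCoords(g)
  blob <- function(cx, cy) {
    dx <- abs(co$X - cx); dx <- pmin(dx, g$Lx - dx)
    dy <- abs(co$Y - cy); dy <- pmin(dy, g$Ly - dy)
    exp(-(dx^2 + dy^2) / 8)
  }
  centre <- c((g$nx - 1) * g$dx / 2, (g$ny - 1) * g$dy / 2)
  expect_equal(unname(periodicCentroid(blob(centre[1], centre[2]), g)),
               centre, tolerance = 1e-8)
  # translation equivariance by whole nodes
  w <- blob(centre[1], centre[2])
  ct <- periodicCentroid(rollMatrix(w, 6, 0), g)
  expect_equal(unname(ct[1]), centre[1] + 6 * g$dx, tolerance = 1e-8)
  expect_equal(unname(ct[2]), centre[2], tolerance = 1e-8)
  # droplet straddling the x = 0 boundary: roll-and-compare oracle
  w0 <- blob(1, 20) # centred near the x boundary
  got <- periodicCentroid(w0, g)
  shifted <- periodicCentroid(rollMatrix(w0, 30, 0), g) # now interior
  expect_equal(unname(got[1]) %% g$Lx, unname(shifted[1] - 30 * g$dx) %% g$Lx,
               tolerance = 1e-8)
  expect_equal(unname(got[2]), unname(shifted[2]), tolerance = 1e-8)
  # degenerate input
  expect_error(periodicCentroid(matrix(0, 64, 64), g), "zero")
  expect_error(periodicCentroid(matrix(-1, 64, 64), g), "non-negative")
})
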