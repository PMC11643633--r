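# Coupled time evolution: initialization, right-hand sides, RK4 stepping,
# the global polarity cue and the compiled engine.

test_that("initial droplet has the right mass, unit polarity inside, determinism", {
  g <- makeGrid(64, 64)
  params <- testParams()
  st <- initializeState(g, params, seed = 3)
  # total actin mass ~ c0 pi R^2 up to the interface-width correction
  expect_equal(sum(st$c) * g$dx * g$dy, params$energy$c0 * pi * params$R^2,
               tolerance = 0.05)
  Pmag <- sqrt(st$P$x^2 + st$P$y^2)
  inside <- st$c >= params$energy$c0 / 2
  expect_true(all(abs(Pmag[inside] - 1) < 1e-12))
  expect_true(all(Pmag[!inside] == 0))
  expect_equal(max(abs(st$v$x), abs(st$v$y), abs(st$omega)), 0)
  # same seed -> bit-identical state
  st2 <- initializeState(g, params, seed = 3)
  expect_identical(st, st2)
  st3 <- initializeState(g, params, seed = 4)
  expect_false(identical(st$P$x, st3$P$x))
  # droplet must fit
  expect_error(initializeState(makeGrid(12, 12), params), "radius")
})

test_that("actin right-hand side conserves mass and is zero for uniform states", {
  g <- makeGrid(32, 32)
  params <- testParams()
  zero <- matrix(0, 32, 32)
  st <- list(t = 0, c = matrix(params$energy$c0, 32, 32), m = zero,
             P = list(x = zero, y = zero), omega = zero, psi = zero,
             v = list(x = zero, y = zero))
  expect_lt(max(abs(rhsC(st, params, g, "fd"))), 1e-13)
  # random state: spatial integral of dc/dt vanishes (divergence theorem)
  st$c <- bandLimitedField(g, 5, 2, 0.3, 0.6)
  st$P <- bandLimitedVector(g, 5, 7, 0.5)
  st$v <- velocityFromStream(bandLimitedField(g, 5, 9), g, "fd")
  expect_lt(abs(sum(rhsC(st, params, g, "fd"))), 1e-10)
  expect_lt(abs(sum(rhsC(st, params, g, "spectral"))), 1e-9)
})

test_that("pure advection translates the droplet at the imposed velocity", {
  # v uniform, M ~ 0, w = 0: after time T the profile is the shifted initial
  # one (the independent oracle is the rolled initial profile)
  g <- makeGrid(64, 64)
  v0 <- 0.5
  params <- modelParams(flow = flowParams(zeta = 0), w = 0, M = 1e-12,
                        dt = 0.125)
  st <- initializeState(g, params, seed = 1)
  st$P <- list(x = matrix(0, 64, 64), y = matrix(0, 64, 64))
  st$m[] <- 0
  st$v$x <- matrix(v0, 64, 64) # imposed uniform flow
  n_steps <- 64 # T = 8, shift = 4 nodes
  for (i in seq_len(n_steps)) {
    k1 <- rhsC(st, params, g, "spectral", dealias = FALSE)
    s2 <- st; s2$c <- st$c + params$dt / 2 * k1
    k2 <- rhsC(s2, params, g, "spectral", dealias = FALSE)
    s3 <- st; s3$c <- st$c + params$dt / 2 * k2
    k3 <- rhsC(s3, params, g, "spectral", dealias = FALSE)
    s4 <- st; s4$c <- st$c + params$dt * k3
    k4 <- rhsC(s4, params, g, "spectral", dealias = FALSE)
    st$c <- st$c + params$dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  shifted <- rollMatrix(initializeState(g, params, seed = 1)$c, 4, 0)
  expect_lt(max(abs(st$c - shifted)), 1e-5)
})

test_that("myosin reaction has the documented fixed points", {
  g <- makeGrid(32, 32)
  params <- testParams()
  zero <- matrix(0, 32, 32)
  inside_c <- matrix(params$energy$c0, 32, 32)
  Dm <- matrix(0, 32, 32)
  # m = m0 inside the cell, no flow and no gradients: reaction balances
  st <- list(t = 0, c = inside_c, m = matrix(params$m0, 32, 32),
             P = list(x = zero, y = zero), omega = zero, psi = zero,
             v = list(x = zero, y = zero))
  expect_lt(max(abs(rhsM(st, Dm, params, g, "fd"))), 1e-13)
  # outside the cell (c = 0), small uniform m decays toward zero
  st$c <- zero; st$m <- matrix(0.1 * params$m0, 32, 32)
  dm <- rhsM(st, Dm, params, g, "fd")
  expect_true(all(dm < 0))
})

test_that("myosin diffusion-reaction matches an independent 1D integrator", {
  # v = 0, P = 0, uniform Dm: the 2D step must reproduce an independent
  # method-of-lines integration of dm/dt = D m'' - (am/Gm)(-s m + m^3/m0^2)
  # on a 1D slice (the field is y-invariant)
  g <- makeGrid(64, 8)
  params <- modelParams(flow = flowParams(zeta = 0), w = 0, dt = 0.1)
  co <- gridCoords(g)
  prof1d <- 0.8 * exp(-((co$x - 32)^2) / 20)
  cline <- matrix(1, g$nx, g$ny) # whole domain counts as cell: sign = +1
  m2d <- matrix(prof1d, g$nx, g$ny)
  D <- 0.3
  Dm <- matrix(D, g$nx, g$ny)
  zero <- matrix(0, g$nx, g$ny)
  st <- list(t = 0, c = cline, m = m2d, P = list(x = zero, y = zero),
             omega = zero, psi = zero, v = list(x = zero, y = zero))
  nstep <- 50
  for (i in seq_len(nstep)) {
    k1 <- rhsM(st, Dm, params, g, "fd")
    s2 <- st; s2$m <- st$m + params$dt / 2 * k1
    k2 <- rhsM(s2, Dm, params, g, "fd")
    s3 <- st; s3$m <- st$m + params$dt / 2 * k2
    k3 <- rhsM(s3, Dm, params, g, "fd")
    s4 <- st; s4$m <- st$m + params$dt * k3
    k4 <- rhsM(s4, Dm, params, g, "fd")
    st$m <- st$m + params$dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  # independent 1D oracle: same physics, separate code path (dense Euler)
  m1 <- prof1d
  n <- length(m1)
  hdt <- params$dt / 500
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  for (i in seq_len(nstep * 500)) {
    lap1 <- (m1[ip] - 2 * m1 + m1[im]) / g$dx^2
    react <- (params$alpha_m / params$Gamma_m) * (-m1 + m1^3 / params$m0^2)
    m1 <- m1 + hdt * (D * lap1 - react)
  }
  # the forward-Euler oracle itself carries O(hdt) error ~ 2e-4
  expect_lt(max(abs(st$m[, 4] - m1)), 1e-3)
})

test_that("the global polarity cue points from the myosin centre to the centroid", {
  g <- makeGrid(64, 64)
  co <- gridCoords(g)
  zero <- matrix(0, 64, 64)
  r <- sqrt((co$X - 31.5)^2 + (co$Y - 31.5)^2)
  c <- 0.5 * (1 - tanh(r - 7))
  # myosin displaced one unit in -x from the cell centre
  rm <- sqrt((co$X - 30.5)^2 + (co$Y - 31.5)^2)
  m <- 0.5 * (1 - tanh(rm - 5))
  st <- list(t = 0, c = c, m = m, P = list(x = zero, y = zero),
             omega = zero, psi = zero, v = list(x = zero, y = zero))
  np <- computeNpolar(st, g, c0 = 1, eps_n = 1e-3)
  expect_equal(unname(np$n[1]), 1, tolerance = 0.05) # cue points along +x
  expect_equal(unname(np$offset[1]), 1, tolerance = 0.1)
  expect_lt(abs(np$offset[2]), 1e-6)
  # brute-force two-centroid oracle for an asymmetric myosin field
  set.seed(4)
  m2 <- ifelse(c >= 0.5, abs(bandLimitedField(g, 3, 7, 0.5, 1)), 0)
  st$m <- m2
  np2 <- computeNpolar(st, g, c0 = 1, eps_n = 0)
  mask <- c >= 0.5
  cc <- periodicCentroid(ifelse(mask, c, 0), g)
  cm <- periodicCentroid(ifelse(mask, m2, 0), g)
  expect_equal(unname(np2$offset), unname(cc - cm), tolerance = 1e-10)
  # perfectly symmetric myosin -> null cue
  st$m <- c
  np3 <- computeNpolar(st, g, c0 = 1, eps_n = 1e-3)
  expect_null(np3$n)
  # and the signed polarization metric follows the construction: a myosin
  # blob strictly inside the support, shifted down-gradient by 2 units
  rm3 <- sqrt((co$X - 31.5)^2 + (co$Y - 29.5)^2)
  st$m <- ifelse(c >= 0.5, 0.5 * (1 - tanh(rm3 - 3)), 0)
  expect_equal(myosinPolarization(st, g, c0 = 1), -2, tolerance = 0.05)
  st$m <- c
  expect_equal(myosinPolarization(st, g, c0 = 1), 0, tolerance = 1e-8)
})

test_that("polarity RHS: equilibrium is stationary and the torque rotates P toward the cue", {
  g <- makeGrid(32, 32)
  zero <- matrix(0, 32, 32)
  params <- testParams(zeta = 0.1) # strong torque for the 0D analysis
  paramsw0 <- modelParams(flow = flowParams(zeta = 0), w = 0, dt = 0.1)
  # uniform c = c0, |P| = 1, no flow, no torque -> rhs = 0
  st <- list(t = 0, c = matrix(1, 32, 32), m = zero,
             P = list(x = zero, y = matrix(1, 32, 32)),
             omega = zero, psi = zero, v = list(x = zero, y = zero))
  dP <- rhsP(st, NULL, paramsw0, g, "fd")
  expect_lt(max(abs(dP$x), abs(dP$y)), 1e-13)
  # P aligned with the cue: no torque contribution
  dP_al <- rhsP(st, list(n = c(0, 1)), params, g, "fd")
  expect_lt(max(abs(dP_al$x), abs(dP_al$y)), 1e-13)
  # P perpendicular to the cue (P parallel to q): the torque rotates P toward
  # the cue at rate zeta while preserving |P| (pure rotation)
  stp <- st
  stp$P <- list(x = matrix(1, 32, 32), y = zero) # P = +x, cue = +y
  dPp <- rhsP(stp, list(n = c(0, 1)), params, g, "fd")
  relax <- rhsP(stp, NULL, params, g, "fd") # molecular-field part alone
  torque_x <- dPp$x - relax$x
  torque_y <- dPp$y - relax$y
  expect_equal(torque_x[5, 5], 0, tolerance = 1e-14)      # no shrinkage of P
  expect_equal(torque_y[5, 5], params$flow$zeta, tolerance = 1e-14) # rotation toward +y
  # magnitude preservation: P . dP_torque = 0 pointwise
  expect_lt(max(abs(stp$P$x * torque_x + stp$P$y * torque_y)), 1e-14)
})

test_that("0D alignment dynamics relax the heading to the cue and not past it", {
  # integrate dP/dt = -zeta (P.q)(R P) for a single vector; the angle to the
  # cue must decrease monotonically to 0 and |P| must stay 1
  zeta <- 0.05
  P <- c(sin(2.5), cos(2.5)) # 143 degrees away from the +y cue
  q <- c(-1, 0) # R times (0, 1)
  ang <- function(P) atan2(P[1], P[2])
  angs <- ang(P)
  for (i in 1:4000) {
    Pq <- sum(P * q)
    RP <- c(-P[2], P[1])
    P <- P - 0.25 * zeta * Pq * RP
    P <- P # no renormalisation: rotation preserves |P| to O(dt^2)
    angs <- c(angs, ang(P))
  }
  expect_true(all(diff(abs(angs)) <= 1e-12))
  expect_lt(abs(angs[length(angs)]), 0.01)
  # forward-Euler rotation inflates the norm only at O(dtheta^2) per step
  expect_equal(sum(P^2), 1, tolerance = 0.05)
})

test_that("a zero-rate step leaves the state unchanged except for time", {
  g <- makeGrid(32, 32)
  # all mobilities/rates ~ 0: state is frozen
  params <- modelParams(energy = energyParams(),
                        flow = flowParams(zeta = 0),
                        M = 1e-300, w = 0, Gamma_P = 1e300, Gamma_m = 1e300,
                        dt = 0.25)
  sub <- makeSubstrate(g, "uniform", E_ref = 70)
  st <- initializeState(g, params, seed = 2)
  st$m[] <- 0 # no myosin: reaction would otherwise act
  out <- rk4Step(st, params, sub, g, "fd", freeze_flow = TRUE)
  expect_equal(out$t, st$t + params$dt)
  expect_lt(max(abs(out$c - st$c)), 1e-12)
  expect_lt(max(abs(out$P$x - st$P$x)), 1e-12)
})

test_that("the compiled engine reproduces the R reference step exactly", {
  g <- makeGrid(32, 32)
  params <- testParams()
  sub <- makeSubstrate(g, "gradient", E_ref = 70, slope = 0.8)
  st <- initializeState(g, params, seed = 9)
  # give the vorticity some content so the flow path is exercised
  st$omega <- bandLimitedField(g, 4, 3, 0.01)
  st$omega <- st$omega - mean(st$omega)
  stR <- st
  for (i in 1:3) stR <- rk4Step(stR, params, sub, g, "fd")
  ctrl <- list(dx = 1, dy = 1, n_steps = 3L, record_every = 1L,
               snapshot_every = 0L, freeze_flow = FALSE)
  res <- durogel:::.dg_engine_run(st$c, st$m, st$P$x, st$P$y, st$omega,
                                  sub$E, unclass(params), ctrl)
  expect_lt(max(abs(res$final$c - stR$c)), 1e-12)
  expect_lt(max(abs(res$final$m - stR$m)), 1e-12)
  expect_lt(max(abs(res$final$Px - stR$P$x)), 1e-12)
  expect_lt(max(abs(res$final$Py - stR$P$y)), 1e-12)
  expect_lt(max(abs(res$final$omega - stR$omega)), 1e-12)
})

test_that("halving the time step improves the solution at 4th order", {
  # passive smooth setting (no myosin, frozen flow) so the only time
  # discretisation error is the RK4 truncation error itself
  g <- makeGrid(32, 32)
  sub <- makeSubstrate(g, "uniform", E_ref = 70)
  run_to <- function(dt, nstep) {
    params <- modelParams(flow = flowParams(zeta = 0), dt = dt)
    st <- initializeState(g, params, seed = 6)
    st$m[] <- 0
    for (i in seq_len(nstep)) {
      st <- rk4Step(st, params, sub, g, "fd", freeze_flow = TRUE)
    }
    st
  }
  ref <- run_to(0.025, 64) # fine-dt reference at T = 1.6
  e1 <- max(abs(run_to(0.2, 8)$c - ref$c))
  e2 <- max(abs(run_to(0.1, 16)$c - ref$c))
  order <- log2(e1 / e2)
  expect_gt(order, 3.3) # classical RK4: ~4 up to roundoff
})

test_that("the pure-R experiment path agrees with the compiled path", {
  cfg <- experimentConfig(grid = makeGrid(32, 32), params = testParams(),
                          substrate_kind = "gradient", E_ref = 70, slope = 0.8,
                          n_steps = 10, record_every = 5, seed = 13,
                          engine = "r")
  cfgC <- cfg; cfgC$engine <- "cpp"
  rR <- runExperiment(cfg)
  rC <- runExperiment(cfgC)
  expect_equal(rR$trajectory$x, rC$trajectory$x, tolerance = 1e-12)
  expect_equal(rR$trajectory$y, rC$trajectory$y, tolerance = 1e-12)
  expect_equal(rR$diagnostics$mass, rC$diagnostics$mass, tolerance = 1e-12)
  expect_equal(rR$diagnostics$energy, rC$diagnostics$energy, tolerance = 1e-10)
  expect_lt(max(abs(rR$final$c - rC$final$c)), 1e-11)
})

test_that("identical configuration and seed reproduce trajectories bit-for-bit", {
  cfg <- experimentConfig(grid = makeGrid(32, 32), params = testParams(),
                          substrate_kind = "gradient", E_ref = 70, slope = 0.8,
                          n_steps = 40, record_every = 10, seed = 21)
  r1 <- runExperiment(cfg)
  r2 <- runExperiment(cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$final$c, r2$final$c)
})
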