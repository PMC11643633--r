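# Shared fixtures: band-limited random periodic fields (no content at or
# above the 2/3 of Nyquist), built from explicit low-order Fourier modes so
# spectral differentiation of them is exact.

bandLimitedField <- function(grid, kmax = 5, seed = 1, amp = 0.3, offset = 0) {
  set.seed(seed)
  co <- gridCoords(grid)
  f <- matrix(offset, grid$nx, grid$ny)
  for (kx in -kmax:kmax) {
    for (ky in 0:kmax) {
      if (kx == 0 && ky == 0) next
      a <- stats::rnorm(2, sd = amp / (1 + kx^2 + ky^2))
      ph <- 2 * pi * (kx * co$X / grid$Lx + ky * co$Y / grid$Ly)
      f <- f + a[1] * cos(ph) + a[2] * sin(ph)
    }
  }
  f
}

bandLimitedVector <- function(grid, kmax = 5, seed = 1, amp = 0.3) {
  list(x = bandLimitedField(grid, kmax, seed, amp),
       y = bandLimitedField(grid, kmax, seed + 1000, amp))
}

# roll a matrix periodically by whole nodes (independent translation oracle)
rollMatrix <- function(m, di, dj) {
  n1 <- nrow(m); n2 <- ncol(m)
  i <- ((seq_len(n1) - 1 - di) %% n1) + 1
  j <- ((seq_len(n2) - 1 - dj) %% n2) + 1
  m[i, j]
}

# reference parameter set used by the simulation tests
testParams <- function(zeta = 0.002, ...) {
  modelParams(flow = flowParams(zeta = zeta), dt = 0.25, ...)
}
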