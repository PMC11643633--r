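## Differential operators on the periodic grid.
##
## Two backends share one interface: "spectral" (FFT differentiation; exact
## for band-limited fields) and "fd" (2nd-order centered differences; this is
## the scheme the time stepper uses, in flux form). Both are periodic and
## translation-equivariant on the torus.

specDeriv <- function(f, grid, axis) {
  K <- gridWavenumbers(grid, deriv = TRUE)
  Km <- if (axis == "x") K$KX else K$KY
  Re(stats::fft(1i * Km * stats::fft(f), inverse = TRUE)) / (grid$nx * grid$ny)
}

fdDeriv <- function(f, grid, axis) {
  if (axis == "x") {
    (f[ixp(grid$nx), , drop = FALSE] - f[ixm(grid$nx), , drop = FALSE]) / (2 * grid$dx)
  } else {
    (f[, ixp(grid$ny), drop = FALSE] - f[, ixm(grid$ny), drop = FALSE]) / (2 * grid$dy)
  }
}

deriv1 <- function(f, grid, axis, scheme) {
  if (scheme == "spectral") specDeriv(f, grid, axis) else fdDeriv(f, grid, axis)
}

#' Gradient of a scalar field
#'
#' Periodic discrete gradient. The mean of each component is exactly zero for
#' any periodic field (both backends).
#'
#' @param f numeric matrix over the grid nodes.
#' @param grid a [makeGrid()] grid.
#' @param scheme `"spectral"` (FFT) or `"fd"` (2nd-order centered).
#' @return vector field: list with matrices `x` and `y`.
#' @export
fieldGradient <- function(f, grid, scheme = c("spectral", "fd")) {
  scheme <- matchScheme(scheme)
  checkField(f, grid)
  list(x = deriv1(f, grid, "x", scheme), y = deriv1(f, grid, "y", scheme))
}

#' Divergence of a vector field
#' @param V vector field (list with matrices `x`, `y`).
#' @inheritParams fieldGradient
#' @return scalar field matrix.
#' @export
fieldDivergence <- function(V, grid, scheme = c("spectral", "fd")) {
  scheme <- matchScheme(scheme)
  checkVectorField(V, grid)
  deriv1(V$x, grid, "x", scheme) + deriv1(V$y, grid, "y", scheme)
}

#' Laplacian of a scalar field
#'
#' The `"fd"` backend uses the standard 5-point stencil (consistent with the
#' Poisson solver and the stream-function velocity map).
#'
#' @inheritParams fieldGradient
#' @return scalar field matrix.
#' @export
fieldLaplacian <- function(f, grid, scheme = c("spectral", "fd")) {
  scheme <- matchScheme(scheme)
  checkField(f, grid)
  if (scheme == "spectral") {
    K <- gridWavenumbers(grid)
    Re(stats::fft(-(K$KX^2 + K$KY^2) * stats::fft(f), inverse = TRUE)) /
      (grid$nx * grid$ny)
  } else {
    ip <- ixp(grid$nx); im <- ixm(grid$nx)
    jp <- ixp(grid$ny); jm <- ixm(grid$ny)
    (f[ip, , drop = FALSE] + f[im, , drop = FALSE] - 2 * f) / grid$dx^2 +
      (f[, jp, drop = FALSE] + f[, jm, drop = FALSE] - 2 * f) / grid$dy^2
  }
}

#' Scalar curl of a 2D vector field
#'
#' Returns the z component of the curl, `dVy/dx - dVx/dy`.
#'
#' @inheritParams fieldDivergence
#' @return scalar field matrix.
#' @export
fieldCurl2d <- function(V, grid, scheme = c("spectral", "fd")) {
  scheme <- matchScheme(scheme)
  checkVectorField(V, grid)
  deriv1(V$y, grid, "x", scheme) - deriv1(V$x, grid, "y", scheme)
}

#' Solve the periodic Poisson equation
#'
#' Finds the zero-mean field `psi` with `laplacian(psi) = rhs`. On the torus
#' the problem is solvable only for (numerically) zero-mean right-hand sides;
#' the zero-mean gauge fixes the free constant. The `"fd"` backend inverts the
#' 5-point Laplacian exactly using its Fourier eigenvalues, so
#' `fieldLaplacian(solvePoisson(rhs, g, "fd"), g, "fd")` reproduces `rhs` to
#' rounding error.
#'
#' @param rhs scalar field matrix with (numerically) zero spatial mean.
#' @inheritParams fieldGradient
#' @param tol solvability tolerance on `|mean(rhs)|` relative to `max(|rhs|)`.
#' @return scalar field matrix `psi` with zero mean.
#' @export
solvePoisson <- function(rhs, grid, scheme = c("spectral", "fd"), tol = 1e-10) {
  scheme <- matchScheme(scheme)
  checkField(rhs, grid)
  scale <- max(abs(rhs), 1)
  if (abs(mean(rhs)) > tol * scale)
    stop("Poisson right-hand side must have zero spatial mean on the torus")
  fh <- stats::fft(rhs)
  lam <- if (scheme == "spectral") {
    K <- gridWavenumbers(grid)
    -(K$KX^2 + K$KY^2)
  } else {
    fdLaplacianEigen(grid)
  }
  lam[1, 1] <- 1 # gauge: zero-mean solution, zero mode discarded
  ph <- fh / lam
  ph[1, 1] <- 0
  Re(stats::fft(ph, inverse = TRUE)) / (grid$nx * grid$ny)
}

#' Velocity from a stream function
#'
#' `v = (dpsi/dy, -dpsi/dx)`; the returned field is divergence-free by
#' construction (exactly so under the `"fd"` backend, since the centered x and
#' y difference stencils commute).
#'
#' @param psi scalar stream-function matrix.
#' @inheritParams fieldGradient
#' @return vector field list with matrices `x`, `y`.
#' @export
velocityFromStream <- function(psi, grid, scheme = c("spectral", "fd")) {
  scheme <- matchScheme(scheme)
  checkField(psi, grid)
  list(x = deriv1(psi, grid, "y", scheme),
       y = -deriv1(psi, grid, "x", scheme))
}

#' Weight centroid on the torus
#'
#' Computes the centroid of a non-negative weight field using the circular
#' mean along each axis, so a droplet straddling the periodic boundary is
#' handled correctly. Coordinates are returned in `[0, Lx) x [0, Ly)`.
#'
#' @param w non-negative weight matrix with positive total weight.
#' @param grid a [makeGrid()] grid.
#' @return numeric `c(x, y)` centroid position.
#' @export
periodicCentroid <- function(w, grid) {
  checkField(w, grid)
  if (any(w < 0)) stop("centroid weights must be non-negative")
  tw <- sum(w)
  if (!(tw > 0)) stop("centroid undefined: total weight is zero")
  co <- gridCoords(grid)
  angX <- 2 * pi * co$X / grid$Lx
  angY <- 2 * pi * co$Y / grid$Ly
  x <- atan2(sum(w * sin(angX)), sum(w * cos(angX))) * grid$Lx / (2 * pi)
  y <- atan2(sum(w * sin(angY)), sum(w * cos(angY))) * grid$Ly / (2 * pi)
  c(x = x %% grid$Lx, y = y %% grid$Ly)
}

## minimal-image difference a - b on the torus, per axis
torusDiff <- function(a, b, L) {
  d <- (a - b) %% L
  ifelse(d > L / 2, d - L, d)
}

## 2/3-rule dealiasing mask (spectral backend, product evaluation)
dealiasMask <- function(grid) {
  kx <- fftWavenumbers(grid$nx, grid$dx)
  ky <- fftWavenumbers(grid$ny, grid$dy)
  mx <- abs(kx) <= (2 / 3) * max(abs(kx))
  my <- abs(ky) <= (2 / 3) * max(abs(ky))
  outer(mx, my, "&")
}

## spectrally filter a real-space product (used by spectral RHS evaluation)
dealiasField <- function(f, grid) {
  m <- dealiasMask(grid)
  Re(stats::fft(m * stats::fft(f), inverse = TRUE)) / (grid$nx * grid$ny)
}
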