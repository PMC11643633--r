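## Stress tensors of the active gel and the incompressible momentum balance
## in vorticity/stream-function form.
##
## Conventions. Tensor fields are lists with components xx, xy, yx, yy where
## sigma_ij is the i force component transported along j, so the body force is
## F_i = d_j sigma_ij. Velocity-gradient tensors use (grad v)_ij = d_i v_j;
## the vorticity Omega_ij = (d_i v_j - d_j v_i)/2 and strain rate
## vbar_ij = (d_i v_j + d_j v_i)/2 carry the conventional 1/2 factors, so for
## a rigid rotation -Omega.P co-rotates P with the flow. Pressure is
## eliminated by taking the scalar curl of the momentum equation:
##   rho (dw/dt + v . grad w) = eta lap w - gamma w + curl(div sigma),
## with w the vorticity; then psi solves lap psi = -w and
## v = (dpsi/dy, -dpsi/dx), which is divergence-free by construction.

#' Flow parameters
#'
#' @param eta shear viscosity (> 0).
#' @param rho fluid density (>= 0); `rho = 0` selects the friction-dominated
#'   Stokes limit in [solveFlow()].
#' @param gamma substrate friction coefficient (>= 0); the only sink of total
#'   momentum on the torus.
#' @param xi flow-alignment shape factor; 1.1 corresponds to shear-aligning
#'   rod-like actin.
#' @param zeta active contractile strength (>= 0); 0.002 is the normal
#'   contractility regime, 0 switches contractility off.
#' @return classed parameter list.
#' @export
flowParams <- function(eta = 0.2, rho = 1, gamma = 0.3, xi = 1.1, zeta = 0.002) {
  stopifnot(eta > 0, rho >= 0, gamma >= 0, is.finite(xi), zeta >= 0)
  structure(list(eta = eta, rho = rho, gamma = gamma, xi = xi, zeta = zeta),
            class = "dg_flow_params")
}

#' Active contractile stress
#'
#' `sigma_act_ij = zeta * c * P_i * P_j`.
#'
#' @param c actin density matrix.
#' @param P polarity vector field.
#' @param zeta contractile strength.
#' @param grid a [makeGrid()] grid.
#' @return tensor field (list `xx`, `xy`, `yx`, `yy`).
#' @export
activeStress <- function(c, P, zeta, grid) {
  checkField(c, grid, "c"); checkVectorField(P, grid, "P")
  list(xx = zeta * c * P$x * P$x, xy = zeta * c * P$x * P$y,
       yx = zeta * c * P$y * P$x, yy = zeta * c * P$y * P$y)
}

#' Elastic (liquid-crystalline) stress
#'
#' `sigma_ela = -1/2 (P h - h P) + (xi/2)(P h + h P)
#'              - kappa (grad P).(grad P)^T`
#' with `h` the molecular field and
#' `[(grad P).(grad P)^T]_ij = sum_k d_i P_k d_j P_k` (the Ericksen term,
#' contracted consistently with the energy).
#'
#' @param P polarity vector field.
#' @param h molecular field, from [molecularField()].
#' @param kappa elastic constant.
#' @param xi shape factor.
#' @param grid a [makeGrid()] grid.
#' @param scheme differentiation backend.
#' @return tensor field.
#' @export
elasticStress <- function(P, h, kappa, xi, grid, scheme = c("spectral", "fd")) {
  scheme <- matchScheme(scheme)
  checkVectorField(P, grid, "P"); checkVectorField(h, grid, "h")
  gPx <- fieldGradient(P$x, grid, scheme)
  gPy <- fieldGradient(P$y, grid, scheme)
  dyad <- function(i, j) -0.5 * (i - j) + (xi / 2) * (i + j)
  list(
    xx = dyad(P$x * h$x, h$x * P$x) - kappa * (gPx$x * gPx$x + gPy$x * gPy$x),
    xy = dyad(P$x * h$y, h$x * P$y) - kappa * (gPx$x * gPx$y + gPy$x * gPy$y),
    yx = dyad(P$y * h$x, h$y * P$x) - kappa * (gPx$y * gPx$x + gPy$y * gPy$x),
    yy = dyad(P$y * h$y, h$y * P$y) - kappa * (gPx$y * gPx$y + gPy$y * gPy$y)
  )
}

#' Interfacial stress
#'
#' `sigma_int = (f - c mu) I - k grad c (x) grad c`, with `f` the free-energy
#' density and `mu` the chemical potential. For a flat 1D interface the
#' discrete identity `int (sigma_xx - sigma_yy) dx = -k int (dc/dx)^2 dx`
#' (the negative of the line tension integral) holds.
#'
#' @param c actin density matrix.
#' @param P polarity vector field.
#' @param grid a [makeGrid()] grid.
#' @param ep [energyParams()].
#' @param scheme differentiation backend.
#' @return tensor field.
#' @export
interfaceStress <- function(c, P, grid, ep, scheme = c("spectral", "fd")) {
  scheme <- matchScheme(scheme)
  f <- freeEnergyDensity(c, P, grid, ep, scheme)
  mu <- chemicalPotential(c, P, grid, ep, scheme)
  gc <- fieldGradient(c, grid, scheme)
  iso <- f - c * mu
  list(xx = iso - ep$k * gc$x * gc$x, xy = -ep$k * gc$x * gc$y,
       yx = -ep$k * gc$y * gc$x, yy = iso - ep$k * gc$y * gc$y)
}

## sum tensor fields elementwise
addTensors <- function(...) {
  ts <- list(...)
  out <- ts[[1]]
  for (t in ts[-1]) for (nm in c("xx", "xy", "yx", "yy")) out[[nm]] <- out[[nm]] + t[[nm]]
  out
}

## scalar curl of the divergence of a tensor field: curl(F), F_i = d_j sigma_ij
stressForceCurl <- function(sig, grid, scheme) {
  Fx <- deriv1(sig$xx, grid, "x", scheme) + deriv1(sig$xy, grid, "y", scheme)
  Fy <- deriv1(sig$yx, grid, "x", scheme) + deriv1(sig$yy, grid, "y", scheme)
  deriv1(Fy, grid, "x", scheme) - deriv1(Fx, grid, "y", scheme)
}

## right-hand side of the vorticity equation (inertial form, rho > 0)
rhsOmega <- function(omega, v, G, fp, grid, scheme) {
  adv <- v$x * deriv1(omega, grid, "x", scheme) + v$y * deriv1(omega, grid, "y", scheme)
  (-fp$rho * adv + fp$eta * fieldLaplacian(omega, grid, scheme) -
     fp$gamma * omega + G) / fp$rho
}

## steady Stokes vorticity: (gamma - eta * lap) w = G, solved spectrally
stokesOmega <- function(G, fp, grid, scheme) {
  Gh <- stats::fft(G)
  lam <- if (scheme == "spectral") {
    K <- gridWavenumbers(grid)
    -(K$KX^2 + K$KY^2)
  } else fdLaplacianEigen(grid)
  Re(stats::fft(Gh / (fp$gamma - fp$eta * lam), inverse = TRUE)) / (grid$nx * grid$ny)
}

## stream function and velocity from a vorticity field
flowFromOmega <- function(omega, grid, scheme) {
  w0 <- omega - mean(omega) # vorticity mean is conserved at 0; guard rounding
  psi <- solvePoisson(-w0, grid, scheme)
  list(psi = psi, v = velocityFromStream(psi, grid, scheme))
}

#' Advance the incompressible flow
#'
#' Advances the vorticity equation by one time step `dt` (classical RK4 on the
#' vorticity with the given frozen stress forcing), or solves the steady
#' friction-dominated Stokes balance when `fp$rho == 0`, then recovers the
#' stream function (`laplacian(psi) = -omega`, zero-mean gauge) and the
#' divergence-free velocity `v = (dpsi/dy, -dpsi/dx)`.
#'
#' @param omega current vorticity matrix (ignored when `fp$rho == 0`).
#' @param stresses total non-viscous stress tensor field (elastic +
#'   interfacial + active), e.g. via [addTensors()] of the three stress
#'   constructors.
#' @param fp [flowParams()].
#' @param dt time step.
#' @param grid a [makeGrid()] grid.
#' @param scheme differentiation backend.
#' @param cfl_limit advective CFL limit `max|v| dt / dx`; exceeding it raises
#'   a warning.
#' @return list with matrices `omega`, `psi` and vector field `v`.
#' @export
solveFlow <- function(omega, stresses, fp, dt, grid,
                      scheme = c("spectral", "fd"), cfl_limit = 0.5) {
  scheme <- matchScheme(scheme)
  checkField(omega, grid, "omega")
  G <- stressForceCurl(stresses, grid, scheme)
  if (fp$rho == 0) {
    omega <- stokesOmega(G, fp, grid, scheme)
  } else {
    fl <- flowFromOmega(omega, grid, scheme)
    k1 <- rhsOmega(omega, fl$v, G, fp, grid, scheme)
    f2 <- flowFromOmega(omega + dt / 2 * k1, grid, scheme)
    k2 <- rhsOmega(omega + dt / 2 * k1, f2$v, G, fp, grid, scheme)
    f3 <- flowFromOmega(omega + dt / 2 * k2, grid, scheme)
    k3 <- rhsOmega(omega + dt / 2 * k2, f3$v, G, fp, grid, scheme)
    f4 <- flowFromOmega(omega + dt * k3, grid, scheme)
    k4 <- rhsOmega(omega + dt * k3, f4$v, G, fp, grid, scheme)
    omega <- omega + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  fl <- flowFromOmega(omega, grid, scheme)
  vmax <- max(abs(fl$v$x), abs(fl$v$y))
  if (vmax * dt / min(grid$dx, grid$dy) > cfl_limit)
    warning(sprintf("advective CFL %.3g exceeds limit %.3g", vmax * dt / min(grid$dx, grid$dy), cfl_limit))
  list(omega = omega, psi = fl$psi, v = fl$v)
}
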