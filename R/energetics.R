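## Free energy of the active polar droplet and its functional derivatives.
##
## The energy density is
##   f = (4a/c0^4) c^2 (c - c0)^2 + (k/2)|grad c|^2
##       - (alpha/2)((2c - c0)/c0)|P|^2 + (alpha/4)|P|^4 + (kappa/2)(grad P)^2
## with (grad P)^2 the full one-constant contraction sum_ij (d_i P_j)^2.
## It makes a polar active phase (c = c0, |P| = 1) coexist with a passive
## solvent phase (c = 0, P = 0); for uniform c in (c0/2, c0] the minimising
## polarity magnitude satisfies |P|^2 = (2c - c0)/c0.
##
## The functional derivatives below are the exact gradients of the *discrete*
## functional (both backends use skew-adjoint first derivatives and
## self-adjoint Laplacians), which is what the functional-derivative oracle in
## the test suite verifies.

#' Free-energy parameters
#'
#' @param a bulk free-energy amplitude (> 0); sets the double-well depth that
#'   separates the actin-rich and solvent phases.
#' @param k interfacial-tension coefficient (> 0) multiplying `|grad c|^2/2`.
#' @param alpha polar bulk coefficient (> 0); couples actin density to the
#'   preferred polarity magnitude.
#' @param kappa one-constant liquid-crystal elastic constant (> 0).
#' @param c0 reference (interior) actin density (> 0).
#' @return classed list of validated parameters.
#' @export
energyParams <- function(a = 1, k = 1.8, alpha = 0.04, kappa = 0.04, c0 = 1) {
  stopifnot(a > 0, k > 0, alpha > 0, kappa > 0, c0 > 0)
  structure(list(a = a, k = k, alpha = alpha, kappa = kappa, c0 = c0),
            class = "dg_energy_params")
}

#' Free-energy density field
#'
#' @param c actin density matrix.
#' @param P polarity vector field (list with matrices `x`, `y`).
#' @param grid a [makeGrid()] grid.
#' @param ep [energyParams()].
#' @param scheme differentiation backend.
#' @return matrix of the energy density at each node.
#' @export
freeEnergyDensity <- function(c, P, grid, ep, scheme = c("spectral", "fd")) {
  scheme <- matchScheme(scheme)
  checkField(c, grid, "c"); checkVectorField(P, grid, "P")
  gc <- fieldGradient(c, grid, scheme)
  gPx <- fieldGradient(P$x, grid, scheme)
  gPy <- fieldGradient(P$y, grid, scheme)
  P2 <- P$x^2 + P$y^2
  (4 * ep$a / ep$c0^4) * c^2 * (c - ep$c0)^2 +
    (ep$k / 2) * (gc$x^2 + gc$y^2) -
    (ep$alpha / 2) * ((2 * c - ep$c0) / ep$c0) * P2 +
    (ep$alpha / 4) * P2^2 +
    (ep$kappa / 2) * (gPx$x^2 + gPx$y^2 + gPy$x^2 + gPy$y^2)
}

## forward-difference |grad f|^2 (the gradient energy whose exact discrete
## gradient is -2 * (5-point Laplacian) f; summed, it is O(dx^2) accurate)
fdForwardGradSq <- function(f, grid) {
  ((f[ixp(grid$nx), , drop = FALSE] - f) / grid$dx)^2 +
    ((f[, ixp(grid$ny), drop = FALSE] - f) / grid$dy)^2
}

#' Total free energy
#'
#' Discrete integral of the free-energy density over the domain. Under the
#' `"fd"` backend the gradient-squared terms are evaluated with forward
#' differences, which makes this functional the exact discrete Lyapunov
#' function of the finite-difference dynamics: [chemicalPotential()] and
#' [molecularField()] with the 5-point Laplacian are then its exact discrete
#' gradients, and the relaxational dynamics decrease it monotonically. Under
#' `"spectral"` the same exactness holds for band-limited (Nyquist-free)
#' fields.
#'
#' @inheritParams freeEnergyDensity
#' @return scalar energy.
#' @export
freeEnergy <- function(c, P, grid, ep, scheme = c("spectral", "fd")) {
  scheme <- matchScheme(scheme)
  if (scheme == "spectral")
    return(sum(freeEnergyDensity(c, P, grid, ep, scheme)) * grid$dx * grid$dy)
  checkField(c, grid, "c"); checkVectorField(P, grid, "P")
  P2 <- P$x^2 + P$y^2
  local <- (4 * ep$a / ep$c0^4) * c^2 * (c - ep$c0)^2 -
    (ep$alpha / 2) * ((2 * c - ep$c0) / ep$c0) * P2 + (ep$alpha / 4) * P2^2
  grads <- (ep$k / 2) * fdForwardGradSq(c, grid) +
    (ep$kappa / 2) * (fdForwardGradSq(P$x, grid) + fdForwardGradSq(P$y, grid))
  sum(local + grads) * grid$dx * grid$dy
}

#' Chemical potential (functional derivative with respect to density)
#'
#' `mu = (8a/c0^4) c (c - c0)(2c - c0) - k laplacian(c) - (alpha/c0)|P|^2`.
#'
#' @inheritParams freeEnergyDensity
#' @return matrix `mu` over the grid.
#' @export
chemicalPotential <- function(c, P, grid, ep, scheme = c("spectral", "fd")) {
  scheme <- matchScheme(scheme)
  checkField(c, grid, "c"); checkVectorField(P, grid, "P")
  (8 * ep$a / ep$c0^4) * c * (c - ep$c0) * (2 * c - ep$c0) -
    ep$k * fieldLaplacian(c, grid, scheme) -
    (ep$alpha / ep$c0) * (P$x^2 + P$y^2)
}

#' Molecular field (functional derivative with respect to polarity)
#'
#' `h = -alpha ((2c - c0)/c0) P + alpha |P|^2 P - kappa laplacian(P)`.
#'
#' @inheritParams freeEnergyDensity
#' @return vector field list with matrices `x`, `y`.
#' @export
molecularField <- function(c, P, grid, ep, scheme = c("spectral", "fd")) {
  scheme <- matchScheme(scheme)
  checkField(c, grid, "c"); checkVectorField(P, grid, "P")
  P2 <- P$x^2 + P$y^2
  pref <- -ep$alpha * (2 * c - ep$c0) / ep$c0 + ep$alpha * P2
  list(x = pref * P$x - ep$kappa * fieldLaplacian(P$x, grid, scheme),
       y = pref * P$y - ep$kappa * fieldLaplacian(P$y, grid, scheme))
}
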