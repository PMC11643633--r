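## Coupled time evolution of the active droplet: actin density c, myosin m,
## polarity P and vorticity omega, advanced together with classical RK4.
##
## The R functions here are the readable reference implementation (used by the
## test suite and for short runs); runExperiment() dispatches to the compiled
## core in src/ which evaluates the identical finite-difference flux-form
## right-hand sides.

#' Full model parameter set
#'
#' Collects every parameter of the active gel model together with the
#' mechanosensing, reaction and numerics parameters. Defaults are the
#' package's frozen reference parameterisation (see the methods vignette for
#' the reasoning); the contractility values `zeta = 0` / `0.002`, shape
#' factor `xi = 1.1`, droplet radius `R = 7`, grid spacing 1 and time step
#' `dt = 0.1` follow the published model setup. The model is normalised with
#' length scale 1 um, time scale 10 ms and force scale 100 nN (bookkeeping
#' only; no parameter below carries explicit units).
#'
#' @param energy [energyParams()].
#' @param flow [flowParams()].
#' @param mech [mechanosenseParams()].
#' @param M thermodynamic mobility of the actin density (> 0).
#' @param w actin polymerization rate (>= 0): self-advection speed of the
#'   droplet along its polarity.
#' @param Gamma_P rotational viscosity of the polarity relaxation (> 0).
#' @param Gamma_m myosin reaction time constant (> 0).
#' @param alpha_m myosin reaction amplitude (> 0); kept independent of the
#'   energy's `alpha`.
#' @param m0 myosin reference density (> 0): the stable interior fixed point
#'   of the reaction term.
#' @param R initial droplet radius (length units).
#' @param eps_int interface half-width of the initial tanh profiles.
#' @param eps_n threshold on the myosin-offset length below which the global
#'   polarity cue `n_polar` is treated as undefined (symmetric myosin).
#' @param dt time step.
#' @param fickian logical: evaluate myosin diffusion as the Fickian
#'   `div(Dm grad m)` instead of the literal `Dm * laplacian(m)` (default
#'   `FALSE`, the literal form).
#' @return classed list of validated parameters.
#' @export
modelParams <- function(energy = energyParams(), flow = flowParams(),
                        mech = mechanosenseParams(),
                        M = 0.02, w = 0.02, Gamma_P = 0.25,
                        Gamma_m = 1, alpha_m = 1, m0 = 1,
                        R = 7, eps_int = 1.0, eps_n = 1e-3,
                        dt = 0.1, fickian = FALSE) {
  stopifnot(M > 0, w >= 0, Gamma_P > 0, Gamma_m > 0, alpha_m > 0, m0 > 0,
            R > 0, eps_int > 0, eps_n > 0, dt > 0)
  structure(list(energy = energy, flow = flow, mech = mech,
                 M = M, w = w, Gamma_P = Gamma_P, Gamma_m = Gamma_m,
                 alpha_m = alpha_m, m0 = m0, R = R, eps_int = eps_int,
                 eps_n = eps_n, dt = dt, fickian = isTRUE(fickian),
                 scales = c(L_um = 1, T_ms = 10, F_nN = 100)),
            class = "dg_model_params")
}

#' @export
print.dg_model_params <- function(x, ...) {
  cat("active gel model parameters\n")
  cat(sprintf("  energy: a=%g k=%g alpha=%g kappa=%g c0=%g\n",
              x$energy$a, x$energy$k, x$energy$alpha, x$energy$kappa, x$energy$c0))
  cat(sprintf("  flow:   eta=%g rho=%g gamma=%g xi=%g zeta=%g\n",
              x$flow$eta, x$flow$rho, x$flow$gamma, x$flow$xi, x$flow$zeta))
  cat(sprintf("  mech:   D0=%g zeta_thr=%g Em=%g E0=%g\n",
              x$mech$D0, x$mech$zeta_thr, x$mech$Em, x$mech$E0))
  cat(sprintf("  other:  M=%g w=%g Gamma_P=%g Gamma_m=%g alpha_m=%g m0=%g R=%g dt=%g\n",
              x$M, x$w, x$Gamma_P, x$Gamma_m, x$alpha_m, x$m0, x$R, x$dt))
  invisible(x)
}

#' Initial field state
#'
#' Places a circular droplet of radius `R` at the domain centre:
#' `c = c0/2 * (1 - tanh((|r - r_c| - R)/eps_int))`, unit-magnitude randomly
#' oriented polarity at every node inside the droplet (`c >= c0/2`) and zero
#' outside, myosin `m = m0` with the same smoothed profile, and quiescent
#' flow. Deterministic given `seed`.
#'
#' @param grid a [makeGrid()] grid.
#' @param params [modelParams()].
#' @param seed integer RNG seed for the random polarity.
#' @return object of class `dg_state`: list with time `t`, matrices `c`, `m`,
#'   `omega`, `psi`, vector fields `P`, `v`.
#' @export
initializeState <- function(grid, params, seed = 1L) {
  if (params$R >= min(grid$Lx, grid$Ly) / 2)
    stop("droplet radius must be smaller than half the domain")
  co <- gridCoords(grid)
  cx <- (grid$nx - 1) * grid$dx / 2
  cy <- (grid$ny - 1) * grid$dy / 2
  r <- sqrt((co$X - cx)^2 + (co$Y - cy)^2)
  c0 <- params$energy$c0
  prof <- 0.5 * (1 - tanh((r - params$R) / params$eps_int))
  cfield <- c0 * prof
  inside <- cfield >= c0 / 2
  set.seed(as.integer(seed))
  theta <- matrix(stats::runif(grid$nx * grid$ny, 0, 2 * pi), grid$nx, grid$ny)
  Px <- ifelse(inside, sin(theta), 0)
  Py <- ifelse(inside, cos(theta), 0)
  zero <- matrix(0, grid$nx, grid$ny)
  structure(list(t = 0, c = cfield, m = params$m0 * prof,
                 P = list(x = Px, y = Py),
                 omega = zero, psi = zero, v = list(x = zero, y = zero)),
            class = "dg_state")
}

#' @export
print.dg_state <- function(x, ...) {
  cat(sprintf("field state at t = %g: total actin %.4g, max |P| %.3g, max m %.3g, max |v| %.3g\n",
              x$t, sum(x$c), sqrt(max(x$P$x^2 + x$P$y^2)), max(x$m),
              max(abs(x$v$x), abs(x$v$y))))
  invisible(x)
}

#' Actin density right-hand side
#'
#' Conservative form of the density evolution:
#' `dc/dt = -div(c (v + w P)) + M laplacian(mu)`. Under the `"fd"` backend
#' the flux divergence telescopes exactly, so the discrete total actin mass
#' is conserved to rounding error.
#'
#' @param state a `dg_state`.
#' @param params [modelParams()].
#' @param grid a [makeGrid()] grid.
#' @param scheme differentiation backend.
#' @param dealias apply the 2/3 rule to the spectral flux products.
#' @return matrix `dc/dt`.
#' @export
rhsC <- function(state, params, grid, scheme = c("spectral", "fd"),
                 dealias = TRUE) {
  scheme <- matchScheme(scheme)
  mu <- chemicalPotential(state$c, state$P, grid, params$energy, scheme)
  fx <- state$c * (state$v$x + params$w * state$P$x)
  fy <- state$c * (state$v$y + params$w * state$P$y)
  if (scheme == "spectral" && dealias) {
    fx <- dealiasField(fx, grid); fy <- dealiasField(fy, grid)
  }
  -fieldDivergence(list(x = fx, y = fy), grid, scheme) +
    params$M * fieldLaplacian(mu, grid, scheme)
}

#' Myosin density right-hand side
#'
#' `dm/dt = -div(m (v - w P)) + Dm * laplacian(m)
#'          - (alpha_m/Gamma_m) (-sign(2c - c0) m + m^3/m0^2)`.
#' The reaction term holds `m` at `m0` inside the cell and drives it to zero
#' outside. `Dm` is evaluated per step from the current cell mask by
#' [myosinDiffusivity()]. With `params$fickian = TRUE` the diffusion term is
#' evaluated as `div(Dm grad m)` instead of the literal form.
#'
#' @param state a `dg_state`.
#' @param Dm diffusivity matrix from [myosinDiffusivity()].
#' @inheritParams rhsC
#' @return matrix `dm/dt`.
#' @export
rhsM <- function(state, Dm, params, grid, scheme = c("spectral", "fd"),
                 dealias = TRUE) {
  scheme <- matchScheme(scheme)
  fx <- state$m * (state$v$x - params$w * state$P$x)
  fy <- state$m * (state$v$y - params$w * state$P$y)
  if (scheme == "spectral" && dealias) {
    fx <- dealiasField(fx, grid); fy <- dealiasField(fy, grid)
  }
  diff_term <- if (params$fickian) {
    gm <- fieldGradient(state$m, grid, scheme)
    fieldDivergence(list(x = Dm * gm$x, y = Dm * gm$y), grid, scheme)
  } else {
    Dm * fieldLaplacian(state$m, grid, scheme)
  }
  sgn <- sign(2 * state$c - params$energy$c0)
  react <- (params$alpha_m / params$Gamma_m) *
    (-sgn * state$m + state$m^3 / params$m0^2)
  -fieldDivergence(list(x = fx, y = fy), grid, scheme) + diff_term - react
}

#' Global polarity cue from the myosin offset
#'
#' The unit vector pointing from the myosin centre of mass (restricted to the
#' cell support) to the cell centroid, both computed with periodic circular
#' means. Returns `NULL` when the offset length is below `eps_n` (symmetric
#' myosin: the alignment torque is disabled for that step) or when the cell
#' carries no myosin.
#'
#' @param state a `dg_state`.
#' @param grid a [makeGrid()] grid.
#' @param c0 reference actin density.
#' @param eps_n offset-length threshold.
#' @return list with unit vector `n` (or `NULL`), the raw `offset` vector and
#'   its `length`.
#' @export
computeNpolar <- function(state, grid, c0, eps_n = 1e-3) {
  mask <- state$c >= c0 / 2
  if (!any(mask)) stop("cell support is empty")
  wc <- ifelse(mask, state$c, 0)
  wm <- ifelse(mask, state$m, 0)
  if (!(sum(wm) > 0)) return(list(n = NULL, offset = c(0, 0), length = 0))
  cc <- unname(periodicCentroid(wc, grid))
  cm <- unname(periodicCentroid(wm, grid))
  off <- c(torusDiff(cc[1], cm[1], grid$Lx), torusDiff(cc[2], cm[2], grid$Ly))
  len <- sqrt(sum(off^2))
  list(n = if (len < eps_n) NULL else off / len, offset = off, length = len)
}

#' Polarity right-hand side
#'
#' `dP/dt = -((v + w P) . grad) P - Omega.P + xi vbar.P - (1/Gamma_P) h
#'          - zeta (P . q)(R_{pi/2} P)`, with `q = R_{pi/2} n_polar`.
#' The last term rotates each local polarity vector towards the global cue
#' `n_polar` at rate `zeta sin(angle)` while preserving its magnitude (both
#' rotations use the same handedness, so the choice of handedness cancels).
#' It is dropped when `npolar` is `NULL`.
#'
#' @param state a `dg_state`.
#' @param npolar output of [computeNpolar()] (or `NULL` to disable the
#'   alignment torque).
#' @inheritParams rhsC
#' @return vector field `dP/dt` (list `x`, `y`).
#' @export
rhsP <- function(state, npolar, params, grid, scheme = c("spectral", "fd")) {
  scheme <- matchScheme(scheme)
  h <- molecularField(state$c, state$P, grid, params$energy, scheme)
  ux <- state$v$x + params$w * state$P$x
  uy <- state$v$y + params$w * state$P$y
  gPx <- fieldGradient(state$P$x, grid, scheme)
  gPy <- fieldGradient(state$P$y, grid, scheme)
  dvxx <- deriv1(state$v$x, grid, "x", scheme)
  dvxy <- deriv1(state$v$y, grid, "x", scheme) # d_x v_y
  dvyx <- deriv1(state$v$x, grid, "y", scheme) # d_y v_x
  dvyy <- deriv1(state$v$y, grid, "y", scheme)
  Oxy <- 0.5 * (dvxy - dvyx)                   # Omega_xy = (d_x v_y - d_y v_x)/2
  Vxx <- dvxx; Vyy <- dvyy; Vxy <- 0.5 * (dvxy + dvyx)
  dPx <- -(ux * gPx$x + uy * gPx$y) -
    (Oxy * state$P$y) + params$flow$xi * (Vxx * state$P$x + Vxy * state$P$y) -
    h$x / params$Gamma_P
  dPy <- -(ux * gPy$x + uy * gPy$y) -
    (-Oxy * state$P$x) + params$flow$xi * (Vxy * state$P$x + Vyy * state$P$y) -
    h$y / params$Gamma_P
  n <- if (is.list(npolar)) npolar$n else npolar
  if (!is.null(n)) {
    zeta <- params$flow$zeta
    # q = R n_polar, RP = R P with the same (counter-clockwise) R
    qx <- -n[2]; qy <- n[1]
    Pq <- state$P$x * qx + state$P$y * qy
    dPx <- dPx - zeta * Pq * (-state$P$y)
    dPy <- dPy - zeta * Pq * (state$P$x)
  }
  list(x = dPx, y = dPy)
}

## per-step frozen quantities: cell mask, sensing, Dm field, npolar cue
stepContext <- function(state, params, substrate, grid) {
  mask <- state$c >= params$energy$c0 / 2
  sense <- senseStiffness(state$c, substrate, params$energy$c0)
  Dm <- myosinDiffusivity(substrate, sense, mask, params$mech, params$flow$zeta)
  np <- computeNpolar(state, grid, params$energy$c0, params$eps_n)
  list(mask = mask, sense = sense, Dm = Dm, npolar = np)
}

## combined RHS for (c, m, P, omega) with flow re-solved from the substage
## vorticity; ctx carries the per-step frozen sensing quantities
rhsState <- function(state, ctx, params, substrate, grid, scheme,
                     freeze_flow = FALSE, dealias = TRUE) {
  fp <- params$flow
  if (freeze_flow) {
    zero <- matrix(0, grid$nx, grid$ny)
    state$v <- list(x = zero, y = zero)
    domega <- zero
  } else {
    fl <- flowFromOmega(state$omega, grid, scheme)
    state$v <- fl$v
    h <- molecularField(state$c, state$P, grid, params$energy, scheme)
    sig <- addTensors(
      elasticStress(state$P, h, params$energy$kappa, fp$xi, grid, scheme),
      interfaceStress(state$c, state$P, grid, params$energy, scheme),
      activeStress(state$c, state$P, fp$zeta, grid)
    )
    G <- stressForceCurl(sig, grid, scheme)
    domega <- rhsOmega(state$omega, state$v, G, fp, grid, scheme)
  }
  list(c = rhsC(state, params, grid, scheme, dealias),
       m = rhsM(state, ctx$Dm, params, grid, scheme, dealias),
       P = rhsP(state, ctx$npolar, params, grid, scheme),
       omega = domega)
}

#' One classical RK4 step of the coupled model (reference implementation)
#'
#' Advances `c`, `m`, `P` and the vorticity simultaneously with classical
#' RK4; the incompressible flow is re-solved from the vorticity at every
#' substage. Stiffness sensing, the myosin diffusivity field and the global
#' polarity cue are evaluated once at the step start (the cell mask moves by
#' far less than a node per step). Negative myosin values arising from
#' advection overshoot are clamped to zero (counted in attribute
#' `"m_clamped"`).
#'
#' @param state a `dg_state`.
#' @param params [modelParams()].
#' @param substrate a [makeSubstrate()] substrate.
#' @param grid a [makeGrid()] grid.
#' @param scheme differentiation backend (the compiled engine uses `"fd"`).
#' @param freeze_flow keep the flow identically zero (passive relaxation
#'   runs).
#' @return the advanced `dg_state` (time advanced by `params$dt`).
#' @export
rk4Step <- function(state, params, substrate, grid,
                    scheme = c("fd", "spectral"), freeze_flow = FALSE) {
  scheme <- match.arg(scheme)
  dt <- params$dt
  ctx <- stepContext(state, params, substrate, grid)
  add <- function(s, k, fac) {
    s2 <- s
    s2$c <- s$c + fac * k$c
    s2$m <- s$m + fac * k$m
    s2$P <- list(x = s$P$x + fac * k$P$x, y = s$P$y + fac * k$P$y)
    s2$omega <- s$omega + fac * k$omega
    s2
  }
  k1 <- rhsState(state, ctx, params, substrate, grid, scheme, freeze_flow)
  k2 <- rhsState(add(state, k1, dt / 2), ctx, params, substrate, grid, scheme, freeze_flow)
  k3 <- rhsState(add(state, k2, dt / 2), ctx, params, substrate, grid, scheme, freeze_flow)
  k4 <- rhsState(add(state, k3, dt), ctx, params, substrate, grid, scheme, freeze_flow)
  out <- state
  out$c <- state$c + dt / 6 * (k1$c + 2 * k2$c + 2 * k3$c + k4$c)
  out$m <- state$m + dt / 6 * (k1$m + 2 * k2$m + 2 * k3$m + k4$m)
  out$P <- list(x = state$P$x + dt / 6 * (k1$P$x + 2 * k2$P$x + 2 * k3$P$x + k4$P$x),
                y = state$P$y + dt / 6 * (k1$P$y + 2 * k2$P$y + 2 * k3$P$y + k4$P$y))
  out$omega <- state$omega + dt / 6 * (k1$omega + 2 * k2$omega + 2 * k3$omega + k4$omega)
  nclamp <- sum(out$m < 0)
  if (nclamp > 0) out$m[out$m < 0] <- 0
  attr(out, "m_clamped") <- nclamp
  if (!freeze_flow) {
    fl <- flowFromOmega(out$omega, grid, scheme)
    out$psi <- fl$psi; out$v <- fl$v
  }
  out$t <- state$t + dt
  if (!all(is.finite(out$c)) || !all(is.finite(out$m)) ||
      !all(is.finite(out$P$x)) || !all(is.finite(out$P$y)) ||
      !all(is.finite(out$omega)))
    stop("simulation failure: non-finite field values at t = ", out$t)
  out
}

#' Myosin polarization along the stiffness gradient
#'
#' Signed projection of (myosin centre - cell centroid) onto the up-gradient
#' unit axis; negative values mean the myosin centre sits on the soft side of
#' the cell.
#'
#' @param state a `dg_state`.
#' @param grid a [makeGrid()] grid.
#' @param c0 reference actin density.
#' @param axis up-gradient axis, `"y"` or `"x"`.
#' @return scalar offset (length units; negative = soft-end polarized).
#' @export
myosinPolarization <- function(state, grid, c0, axis = c("y", "x")) {
  axis <- match.arg(axis)
  np <- computeNpolar(state, grid, c0, eps_n = 0)
  # offset = cell centroid - myosin centre; polarization = -(offset . axis)
  if (axis == "y") -np$offset[2] else -np$offset[1]
}
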