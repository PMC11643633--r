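## Substrate stiffness maps, cell stiffness sensing and the mechanosensitive
## myosin diffusivity Dm(E).

#' Mechanosensing parameters
#'
#' Parameters of the stiffness-dependent myosin diffusivity
#' `Dm(E) = (zeta*D0/zeta_thr) * ((E - Emin)/(Emax - Emin))^2 *
#'          (1 - 1/(1 + exp((Em - Eaver)/E0)))`
#' applied inside the cell; outside the cell the diffusivity is the basal
#' `D0`. `Emin`, `Emax`, `Eaver` are the extreme and mean stiffness currently
#' sensed under the cell (`c >= c0/2`).
#'
#' @param D0 basal diffusion parameter (>= 0), simulation units.
#' @param zeta_thr contractility threshold (> 0) normalising the active
#'   contractile strength.
#' @param Em stiffness-sensitivity threshold (kPa): the sigmoid gate is 1/2
#'   when the cell-averaged stiffness equals `Em`.
#' @param E0 reference stiffness (kPa, > 0) setting the gate width.
#' @return classed parameter list.
#' @export
mechanosenseParams <- function(D0 = 0.3, zeta_thr = 0.001, Em = 85, E0 = 15) {
  stopifnot(D0 >= 0, zeta_thr > 0, E0 > 0)
  structure(list(D0 = D0, zeta_thr = zeta_thr, Em = Em, E0 = E0),
            class = "dg_mech_params")
}

#' Build a substrate stiffness map
#'
#' Either a uniform map `E = E_ref` or a linear gradient
#' `E(r) = E_ref + slope * (coordinate - domain centre coordinate)` along the
#' chosen axis. Stiffness must stay positive over the whole domain.
#'
#' @param grid a [makeGrid()] grid.
#' @param kind `"uniform"` or `"gradient"`.
#' @param E_ref stiffness (kPa) at the domain centre.
#' @param slope gradient steepness in kPa per length unit (kPa/um); positive
#'   slope means stiffer towards larger coordinates.
#' @param axis gradient axis, `"y"` (the conventional up-gradient axis) or `"x"`.
#' @return object of class `dg_substrate`: list with `grid`, `E` matrix (kPa),
#'   and the construction spec.
#' @export
makeSubstrate <- function(grid, kind = c("uniform", "gradient"),
                          E_ref = 70, slope = 0.8, axis = c("y", "x")) {
  kind <- match.arg(kind); axis <- match.arg(axis)
  stopifnot(is.finite(E_ref))
  co <- gridCoords(grid)
  E <- if (kind == "uniform") {
    matrix(E_ref, grid$nx, grid$ny)
  } else {
    coord <- if (axis == "x") co$X else co$Y
    centre <- if (axis == "x") (grid$nx - 1) * grid$dx / 2 else (grid$ny - 1) * grid$dy / 2
    E_ref + slope * (coord - centre)
  }
  if (any(E <= 0))
    stop("substrate configuration gives non-positive stiffness; reduce |slope| or raise E_ref")
  structure(list(grid = grid, E = E, kind = kind, E_ref = E_ref,
                 slope = if (kind == "uniform") 0 else slope, axis = axis),
            class = "dg_substrate")
}

#' @export
print.dg_substrate <- function(x, ...) {
  cat(sprintf("substrate: %s, E_ref = %g kPa, slope = %g kPa/um (axis %s), range [%.3g, %.3g] kPa\n",
              x$kind, x$E_ref, x$slope, x$axis, min(x$E), max(x$E)))
  invisible(x)
}

#' Load a substrate map from a CSV matrix
#'
#' Raster override for [makeSubstrate()]: reads a headerless CSV of stiffness
#' values (kPa) with `nx` rows and `ny` columns matching the grid.
#'
#' @param path CSV file path.
#' @param grid a [makeGrid()] grid.
#' @return `dg_substrate` object of kind `"raster"`.
#' @export
readSubstrateCsv <- function(path, grid) {
  E <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(E) <- NULL
  checkField(E, grid, "substrate raster")
  if (any(E <= 0)) stop("substrate raster contains non-positive stiffness")
  structure(list(grid = grid, E = E, kind = "raster", E_ref = mean(E),
                 slope = NA_real_, axis = NA_character_),
            class = "dg_substrate")
}

#' Stiffness sensed by the cell
#'
#' Minimum, maximum and mean substrate stiffness over the cell support
#' `{c >= c0/2}`.
#'
#' @param c actin density matrix.
#' @param sub a [makeSubstrate()] substrate.
#' @param c0 reference actin density.
#' @return list with `Emin`, `Emax`, `Eaver` (kPa).
#' @export
senseStiffness <- function(c, sub, c0) {
  mask <- c >= c0 / 2
  if (!any(mask))
    stop("cell support is empty (c >= c0/2 nowhere): the droplet has dissolved")
  Es <- sub$E[mask]
  list(Emin = min(Es), Emax = max(Es), Eaver = mean(Es))
}

#' Mechanosensitive myosin diffusivity field
#'
#' Outside the cell the diffusivity equals the basal `D0`. Inside, it follows
#' the quadratic-times-sigmoid law documented in [mechanosenseParams()], which
#' vanishes at the softest point under the cell and is gated off when the
#' cell-averaged stiffness is far above the sensitivity threshold `Em`. When
#' the cell senses no stiffness contrast (`Emax == Emin`, e.g. a uniform
#' substrate) the quadratic factor is defined as zero, so no stiffness-derived
#' asymmetry can arise; this degenerate case is flagged via the
#' `"degenerate"` attribute rather than an error.
#'
#' @param sub a [makeSubstrate()] substrate.
#' @param sense output of [senseStiffness()].
#' @param mask logical matrix of the cell support (`c >= c0/2`).
#' @param mp [mechanosenseParams()].
#' @param zeta active contractile strength (>= 0).
#' @return diffusivity matrix (>= 0 everywhere), with attribute `degenerate`.
#' @export
myosinDiffusivity <- function(sub, sense, mask, mp, zeta) {
  degenerate <- sense$Emax <= sense$Emin
  Dm <- matrix(mp$D0, nrow(sub$E), ncol(sub$E))
  if (degenerate) {
    Dm[mask] <- 0
  } else {
    quad <- ((sub$E - sense$Emin) / (sense$Emax - sense$Emin))^2
    gate <- 1 - 1 / (1 + exp((mp$Em - sense$Eaver) / mp$E0))
    inside <- (zeta * mp$D0 / mp$zeta_thr) * quad * gate
    Dm[mask] <- pmax(inside[mask], 0)
  }
  attr(Dm, "degenerate") <- degenerate
  Dm
}
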