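#' Periodic simulation grid
#'
#' Construct the square periodic grid all fields live on. Fields are stored as
#' plain numeric matrices indexed `[i, j]` with `i` the x node and `j` the
#' y node; node coordinates are `x_i = (i-1)*dx`, `y_j = (j-1)*dy`, so the
#' domain is the torus `[0, Lx) x [0, Ly)`. One length unit corresponds to
#' 1 micrometre under the model's normalisation.
#'
#' @param nx,ny integer number of nodes in x and y (at least 8).
#' @param dx,dy node spacing in length units (default 1).
#' @return an object of class `dg_grid`: a list with `nx`, `ny`, `dx`, `dy`
#'   and the domain lengths `Lx = nx*dx`, `Ly = ny*dy`.
#' @examples
#' g <- makeGrid(64, 64)
#' g$Lx
#' @export
makeGrid <- function(nx, ny = nx, dx = 1, dy = dx) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 8L || ny < 8L) stop("grid must have at least 8 nodes per axis")
  if (!(dx > 0) || !(dy > 0)) stop("grid spacing must be positive")
  structure(
    list(nx = nx, ny = ny, dx = dx, dy = dy, Lx = nx * dx, Ly = ny * dy),
    class = "dg_grid"
  )
}

#' @export
print.dg_grid <- function(x, ...) {
  cat(sprintf("periodic grid: %d x %d nodes, dx = %g, dy = %g (domain %g x %g)\n",
              x$nx, x$ny, x$dx, x$dy, x$Lx, x$Ly))
  invisible(x)
}

#' Node coordinate matrices
#'
#' @param grid a [makeGrid()] grid.
#' @return list with vectors `x`, `y` and matrices `X`, `Y` of node coordinates.
#' @export
gridCoords <- function(grid) {
  x <- (seq_len(grid$nx) - 1) * grid$dx
  y <- (seq_len(grid$ny) - 1) * grid$dy
  list(x = x, y = y,
       X = matrix(x, grid$nx, grid$ny),
       Y = matrix(y, grid$nx, grid$ny, byrow = TRUE))
}

## angular wavenumbers in FFT ordering (k = 2*pi*f)
fftWavenumbers <- function(n, d) {
  half <- floor((n - 1) / 2)
  f <- c(0:half, -(n - half - 1):-1) / (n * d)
  2 * pi * f
}

## wavenumber matrices for a grid; deriv = TRUE zeroes the Nyquist mode
## (odd derivative of a real field has no well-defined Nyquist contribution)
gridWavenumbers <- function(grid, deriv = FALSE) {
  kx <- fftWavenumbers(grid$nx, grid$dx)
  ky <- fftWavenumbers(grid$ny, grid$dy)
  if (deriv) {
    if (grid$nx %% 2 == 0) kx[grid$nx / 2 + 1] <- 0
    if (grid$ny %% 2 == 0) ky[grid$ny / 2 + 1] <- 0
  }
  list(KX = matrix(kx, grid$nx, grid$ny),
       KY = matrix(ky, grid$nx, grid$ny, byrow = TRUE))
}

## eigenvalues of the 5-point periodic FD Laplacian, FFT ordering
fdLaplacianEigen <- function(grid) {
  lx <- (2 * cos(2 * pi * (seq_len(grid$nx) - 1) / grid$nx) - 2) / grid$dx^2
  ly <- (2 * cos(2 * pi * (seq_len(grid$ny) - 1) / grid$ny) - 2) / grid$dy^2
  matrix(lx, grid$nx, grid$ny) + matrix(ly, grid$nx, grid$ny, byrow = TRUE)
}

checkField <- function(f, grid, what = "field") {
  if (!is.matrix(f) || nrow(f) != grid$nx || ncol(f) != grid$ny)
    stop(what, " must be a ", grid$nx, " x ", grid$ny, " matrix")
  if (!all(is.finite(f))) stop(what, " contains non-finite values")
  invisible(f)
}

checkVectorField <- function(V, grid, what = "vector field") {
  if (!is.list(V) || is.null(V$x) || is.null(V$y))
    stop(what, " must be a list with components x and y")
  checkField(V$x, grid, paste(what, "(x)"))
  checkField(V$y, grid, paste(what, "(y)"))
  invisible(V)
}

## periodic index shifts for centered differences
ixp <- function(n) c(2:n, 1L)
ixm <- function(n) c(n, 1:(n - 1L))

matchScheme <- function(scheme) match.arg(scheme, c("spectral", "fd"))
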