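#' Periodic Eulerian fluid grid
#'
#' Allocates the square periodic grid that carries the viscous incompressible
#' fluid in which all cell boundaries are immersed. Node `(i, j)` (1-based)
#' sits at `((i-1)*h, (j-1)*h)` with mesh width `h = length_um / n`. The grid
#' stores velocity (`u`, `v`), pressure `p`, body-force density (`fx`, `fy`)
#' and the local fluid expansion (source) field `s`.
#'
#' @param n nodes per axis; must be a power of two (the Stokes solve is
#'   spectral).
#' @param length_um physical edge length of the periodic box (micrometres).
#' @param mu fluid viscosity. Only the ratio of boundary forces to `mu`
#'   matters for the resulting velocities, so it is kept at 1 by default and
#'   the spring constants carry the units.
#' @param rho fluid density. The default 0 selects the quasi-static Stokes
#'   regime (inertia dropped); a positive value enables the semi-implicit
#'   unsteady term.
#' @return an object of class `fluid_grid`.
#' @export
fluid_grid <- function(n = 128L, length_um = 80, mu = 1, rho = 0) {
  n <- as.integer(n)
  if (n < 4L || bitwAnd(n, n - 1L) != 0L)
    stop("grid size `n` must be a power of two >= 4")
  if (length_um <= 0 || mu <= 0 || rho < 0)
    stop("invalid fluid parameters")
  h <- length_um / n
  z <- matrix(0, n, n)
  g <- list(
    n = n, h = h, length_um = length_um, mu = mu, rho = rho,
    u = z, v = z, p = z, fx = z, fy = z, s = z,
    sym = stokes_symbols(n, h)
  )
  class(g) <- "fluid_grid"
  g
}

# Fourier symbols of the centred-difference derivative and five-point
# Laplacian; cached in the grid so a solve is two ffts + algebra.
stokes_symbols <- function(n, h) {
  j <- 0:(n - 1)
  kh <- 2 * pi * j / n
  d1 <- 1i * sin(kh) / h              # centred first derivative
  lap1 <- (2 * cos(kh) - 2) / h^2     # 1D discrete Laplacian
  Dx <- matrix(d1, n, n)
  Dy <- matrix(d1, n, n, byrow = TRUE)
  Lap <- matrix(lap1, n, n) + matrix(lap1, n, n, byrow = TRUE)
  sig <- (Im(Dx))^2 + (Im(Dy))^2      # |D|^2, real and >= 0
  list(Dx = Dx, Dy = Dy, Lap = Lap, sig = sig, null = sig <= 0)
}

#' @export
print.fluid_grid <- function(x, ...) {
  cat(sprintf(
    "<fluid_grid> %d x %d periodic, h = %.4g um, L = %g um, mu = %g, rho = %g\n",
    x$n, x$n, x$h, x$length_um, x$mu, x$rho))
  cat(sprintf("  max |u| = %.3g, sum s = %.3g\n",
              max(abs(x$u), abs(x$v)), sum(x$s)))
  invisible(x)
}

#' Regularized delta weight
#'
#' One-dimensional 4-point cosine kernel used to couple Lagrangian boundary
#' points to the Eulerian grid: `(1/4)(1 + cos(pi r / 2))` for `|r| < 2`
#' (mesh-width units), zero outside. The 2D weight is the product of two 1D
#' evaluations. The kernel is a partition of unity over grid offsets and its
#' even and odd translates each sum to 1/2, which removes the checkerboard
#' null space of the centred-difference divergence.
#'
#' @param r offset in mesh-width units (vectorized).
#' @return numeric weights.
#' @export
delta_weight <- function(r) {
  w <- numeric(length(r))
  in_support <- abs(r) < 2
  w[in_support] <- 0.25 * (1 + cos(pi * r[in_support] / 2))
  w
}

#' Spread point values onto the grid
#'
#' Accumulates per-point forces or source strengths onto grid fields using the
#' regularized delta: each point adds `value * w / h^2` to the 4x4 stencil of
#' surrounding nodes, so the discrete grid integral (`sum(field) * h^2`)
#' equals the sum of point values.
#'
#' @param grid a [fluid_grid()].
#' @param positions m x 2 matrix of point coordinates (micrometres).
#' @param values for `target = "source"` a length-m vector of source
#'   strengths; for `target = "force"` an m x 2 matrix of force components.
#' @param target which field to accumulate into.
#' @param reset zero the target field(s) first (default TRUE).
#' @return the updated grid.
#' @export
spread <- function(grid, positions, values, target = c("force", "source"),
                   reset = TRUE) {
  target <- match.arg(target)
  positions <- as_positions(positions, grid$length_um)
  if (target == "source") {
    values <- as.numeric(values)
    stopifnot(length(values) == nrow(positions))
    f <- spread_scalar_cpp(positions[, 1], positions[, 2], values,
                           grid$n, grid$h)
    grid$s <- if (reset) f else grid$s + f
  } else {
    values <- as.matrix(values)
    stopifnot(nrow(values) == nrow(positions), ncol(values) == 2)
    f <- spread_vector_cpp(positions[, 1], positions[, 2],
                           values[, 1], values[, 2], grid$n, grid$h)
    if (reset) {
      grid$fx <- f$fx; grid$fy <- f$fy
    } else {
      grid$fx <- grid$fx + f$fx; grid$fy <- grid$fy + f$fy
    }
  }
  grid
}

as_positions <- function(positions, L) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2) stop("positions must be an m x 2 matrix")
  if (any(!is.finite(positions)))
    stop("non-finite point position", call. = FALSE)
  positions %% L
}

#' Solve one fluid step
#'
#' Given the assembled force density and source field, computes the velocity
#' and pressure of the viscous incompressible fluid on the periodic grid. In
#' the default quasi-static regime (`rho = 0`) this is the steady Stokes
#' problem `mu lap(u) - grad(p) + f = 0` with the mass-balance constraint
#' `div(u) = s`; with `rho > 0` a semi-implicit viscosity step is taken and
#' the advective term is dropped (boundaries move far less than one mesh
#' width per step). Derivatives are centred differences diagonalized in
#' Fourier space, so the centred-difference divergence of the returned
#' velocity equals `s` at every node to round-off.
#'
#' @param grid a [fluid_grid()] with `fx`, `fy`, `s` filled.
#' @param dt time step (hours); only used when `rho > 0`.
#' @return the grid with `u`, `v`, `p` updated.
#' @export
solve_fluid_step <- function(grid, dt = 1) {
  n <- grid$n
  sym <- grid$sym
  a <- if (grid$rho > 0) grid$rho / dt else 0
  A <- a - grid$mu * sym$Lap          # >= 0; zero only at k = 0 when a = 0
  gx <- stats::fft(grid$fx)
  gy <- stats::fft(grid$fy)
  sh <- stats::fft(grid$s)
  if (a > 0) {
    gx <- gx + a * stats::fft(grid$u)
    gy <- gy + a * stats::fft(grid$v)
  }
  div_g <- sym$Dx * gx + sym$Dy * gy
  ph <- (A * sh - div_g) / sym$sig
  ph[sym$null] <- 0
  uh <- (gx - sym$Dx * ph)
  vh <- (gy - sym$Dy * ph)
  Asafe <- A
  Asafe[A == 0] <- 1
  uh <- uh / Asafe
  vh <- vh / Asafe
  uh[A == 0] <- 0
  vh[A == 0] <- 0
  grid$u <- Re(stats::fft(uh, inverse = TRUE)) / n^2
  grid$v <- Re(stats::fft(vh, inverse = TRUE)) / n^2
  grid$p <- Re(stats::fft(ph, inverse = TRUE)) / n^2
  if (any(!is.finite(grid$u)) || any(!is.finite(grid$v)))
    stop(ibcell_condition("ibcell_blowup", "non-finite velocity field"))
  grid
}

#' Centred-difference divergence of the grid velocity
#'
#' The discrete divergence operator matched to the solver; after
#' [solve_fluid_step()] it reproduces the source field `s` node-for-node.
#'
#' @param grid a solved [fluid_grid()].
#' @return an n x n matrix.
#' @export
grid_divergence <- function(grid) {
  n <- grid$n
  ip <- c(2:n, 1)
  im <- c(n, 1:(n - 1))
  (grid$u[ip, ] - grid$u[im, ]) / (2 * grid$h) +
    (grid$v[, ip] - grid$v[, im]) / (2 * grid$h)
}

#' Interpolate grid velocity at boundary points
#'
#' Delta-weighted average of nearby node velocities; the discrete adjoint of
#' [spread()] (up to the `h^2` quadrature factor), so spreading and
#' interpolation conserve energy pairings exactly.
#'
#' @param grid a solved [fluid_grid()].
#' @param positions m x 2 matrix of point coordinates.
#' @return m x 2 matrix of velocities.
#' @export
interpolate_velocity <- function(grid, positions) {
  positions <- as_positions(positions, grid$length_um)
  interp_vector_cpp(grid$u, grid$v, positions[, 1], positions[, 2], grid$h)
}

#' Advect points with the local fluid velocity
#'
#' Forward-Euler update with periodic wrap. A displacement above one mesh
#' width in a single step signals that the step size is too large for the
#' current forces.
#'
#' @param positions m x 2 matrix.
#' @param velocities m x 2 matrix from [interpolate_velocity()].
#' @param dt time step (hours).
#' @param grid the [fluid_grid()] (for the box length and mesh width).
#' @param warn warn when the CFL-like displacement bound is exceeded.
#' @return m x 2 matrix of new, wrapped positions.
#' @export
advect <- function(positions, velocities, dt, grid, warn = TRUE) {
  disp <- velocities * dt
  dmax <- max(abs(disp), 0)
  if (warn && dmax > grid$h)
    warning(sprintf("boundary displacement %.3g um exceeds mesh width", dmax))
  (positions + disp) %% grid$length_um
}

ibcell_condition <- function(class, msg, ...) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = sys.call(-1), ...))
}
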