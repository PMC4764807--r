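#' Barkley model and grid parameters
#'
#' Bundles the kinetic constants of the Barkley excitable medium with the
#' numerical grid settings.  The kinetics are
#' \deqn{\partial_t u = \frac{1}{\varepsilon} u (1-u)\left(u - \frac{v+b}{a}\right) + \nabla^2 u,
#'       \qquad \partial_t v = u - v,}
#' where \eqn{u} is the fast (membrane-potential-like) variable and \eqn{v}
#' the slow recovery variable.  The defaults \eqn{a = 0.9}, \eqn{b = 0.08},
#' \eqn{\varepsilon = 0.02} put the medium in the rigidly-rotating-spiral /
#' collapsing-scroll-rings regime: spirals rotate rigidly and closed scroll
#' filaments have positive tension.
#'
#' The explicit Euler / central-difference scheme requires
#' \eqn{dt \le dx^2/6} for the 3D Laplacian; the default time step is
#' \code{min(0.8 * dx^2 / 6, 0.002)}, the second bound keeping the stiff
#' reaction term (rate \eqn{1/\varepsilon}) accurate.
#'
#' @param a Excitability parameter (dimensionless), > 0.
#' @param b Threshold offset (dimensionless), >= 0.
#' @param epsilon Time-scale separation (dimensionless), > 0.
#' @param dx Grid spacing (space units).
#' @param dt Time step (time units); default as described above.
#' @param grid Integer triple (nx, ny, nz).
#'
#' @return An object of class \code{"model_params"}.
#' @examples
#' p <- model_params(grid = c(40, 40, 40))
#' p$dt
#' @export
model_params <- function(a = 0.9, b = 0.08, epsilon = 0.02,
                         dx = 0.25, dt = NULL,
                         grid = c(60L, 60L, 60L)) {
  stopifnot(is.numeric(a), length(a) == 1, a > 0)
  stopifnot(is.numeric(b), length(b) == 1, b >= 0)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1, epsilon > 0)
  stopifnot(is.numeric(dx), length(dx) == 1, dx > 0)
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3, all(grid >= 3))
  if (is.null(dt)) dt <- min(0.8 * dx^2 / 6, 0.002)
  stopifnot(is.numeric(dt), length(dt) == 1, dt > 0)
  if (dt > dx^2 / 6 + 1e-12) {
    stop("dt = ", dt, " violates the diffusion stability bound dx^2/6 = ",
         dx^2 / 6)
  }
  structure(list(a = a, b = b, epsilon = epsilon, dx = dx, dt = dt,
                 grid = grid),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Barkley model parameters\n")
  cat(sprintf("  a = %g, b = %g, epsilon = %g\n", x$a, x$b, x$epsilon))
  cat(sprintf("  grid %d x %d x %d, dx = %g, dt = %g\n",
              x$grid[1], x$grid[2], x$grid[3], x$dx, x$dt))
  invisible(x)
}

#' Physical coordinates of grid planes along one axis
#'
#' Grid point i (1-based) sits at (i - 1) * dx.
#' @param params A \code{model_params} object.
#' @param axis 1, 2 or 3.
#' @return Numeric vector of coordinates.
#' @export
grid_coords <- function(params, axis) {
  (seq_len(params$grid[axis]) - 1) * params$dx
}

#' Center of the simulation box in space units
#' @param params A \code{model_params} object.
#' @return Length-3 numeric vector.
#' @export
grid_center <- function(params) {
  (params$grid - 1) / 2 * params$dx
}

#' Pointwise Barkley reaction rates
#'
#' Evaluates the local kinetics \eqn{\dot u_{react} = (1/\varepsilon)
#' u(1-u)(u-(v+b)/a)} and \eqn{\dot v = u - v}.  Vectorized over \code{u}
#' and \code{v}; applied elementwise over fields by the stepper.
#'
#' @param u,v Numeric scalars or arrays of identical shape.
#' @param params A \code{model_params} object.
#' @return List with components \code{du} and \code{dv}.
#' @examples
#' barkley_reaction(0.5, 0.1, model_params())  # du = 3.75, dv = 0.4
#' @export
barkley_reaction <- function(u, v, params) {
  du <- (1 / params$epsilon) * u * (1 - u) * (u - (v + params$b) / params$a)
  list(du = du, dv = u - v)
}
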