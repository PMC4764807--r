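# Independent ghost-node / closed-form references for the Neumann
# boundary treatment.  These never call the package's phase-field path.
#
# Sign convention note: the stepper adds + (1/phi)(grad phi . E).  In
# steady state phi*du/dx + phi*E = const = 0 (phi -> 0 in the obstacle),
# so the emergent boundary condition on the tissue side is
# n . grad u = - n . E with n the outward (into-tissue) normal: the face
# the field vector points toward is depolarized.  The references below
# implement that same condition explicitly.

# 1D diffusion-only slab: tissue on [x0, L], Neumann du/dx = slope at the
# left (obstacle) end via a ghost node, u = 0 clamped at the right end.
# Explicit Euler to (near) steady state; returns the profile on xs.
ghost_node_slab <- function(xs, slope_left, dt = 0.01, t_end = 150) {
  n <- length(xs)
  dx <- xs[2] - xs[1]
  u <- numeric(n)
  nsteps <- ceiling(t_end / dt)
  for (s in seq_len(nsteps)) {
    ug <- u[2] - 2 * dx * slope_left       # central-difference Neumann
    lap <- c(u[2] + ug - 2 * u[1],
             u[-c(1, 2)] + u[-c(n - 1, n)] - 2 * u[-c(1, n)],
             0)
    u <- u + dt * lap / dx^2
    u[n] <- 0
  }
  u
}

# 2D disk: steady diffusion around a disk of radius R with boundary
# condition du/dr|R = -E0 cos(az) and u = 0 on the circle r = Rout.
# Separable harmonic solution u = f(r) cos(az), f = alpha (r - Rout^2/r).
disk_closed_form <- function(r, az, R, Rout, E0) {
  alpha <- -E0 / (1 + Rout^2 / R^2)
  alpha * (r - Rout^2 / r) * cos(az)
}

# Drive the package's diffusion+forcing operator (no reaction) to steady
# state, clamping u = 0 where `sink` is TRUE.  Used on slab and disk
# geometries against the references above.
pf_diffusion_steady <- function(domain, params, E, sink,
                                dt = 0.01, t_end = 150) {
  u <- array(0, dim = params$grid)
  nsteps <- ceiling(t_end / dt)
  for (s in seq_len(nsteps)) {
    u <- u + dt * diffusion_and_forcing(u, domain, E, params)
    u[sink] <- 0
  }
  u
}
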