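# Shared small grids and hand-built phase-field domains for tests.
# Test-scale study conditions: 60^3 grid, dx = 0.25, obstacle R = 2.5.

test_params <- function(grid = c(40, 40, 40), ...) {
  model_params(grid = grid, ...)
}

# Build a phase_field_domain from an arbitrary phi array (same
# precomputations as build_phase_field), for slab/cylinder geometries the
# constructor does not cover.
domain_from_phi <- function(phi, params, center = grid_center(params),
                            radius = 0, floor = 0.002) {
  phi <- array(phi, dim = params$grid)
  active <- array(as.integer(phi >= floor), dim = dim(phi))
  invphi <- array(0, dim = dim(phi))
  invphi[active == 1L] <- 1 / phi[active == 1L]
  gop <- function(axis) {
    n <- dim(phi)[axis]
    hi <- c(2:n, n); lo <- c(1, 1:(n - 1))
    g <- switch(axis,
                phi[hi, , ] - phi[lo, , ],
                phi[, hi, ] - phi[, lo, ],
                phi[, , hi] - phi[, , lo])
    g / (2 * params$dx) * invphi
  }
  structure(list(phi = phi, center = center, radius = radius,
                 interface_width = 2 * params$dx, floor = floor,
                 active = active, invphi = invphi,
                 gx = gop(1), gy = gop(2), gz = gop(3)),
            class = "phase_field_domain")
}

# 1D slab phase field along x: obstacle at x < x0 (phi rises with x),
# replicated over y, z.
slab_domain <- function(params, x0, width = 2 * params$dx) {
  xs <- grid_coords(params, 1)
  phi1 <- 0.5 * (1 + tanh((xs - x0) / width))
  phi1[xs >= x0 + 5 * width] <- 1
  domain_from_phi(rep(phi1, times = prod(params$grid[2:3])), params)
}

# Cylindrical (z-invariant) disk obstacle of radius R at the grid center.
disk_domain <- function(params, radius, width = 2 * params$dx) {
  ctr <- grid_center(params)
  xs <- grid_coords(params, 1) - ctr[1]
  ys <- grid_coords(params, 2) - ctr[2]
  r <- sqrt(outer(xs^2, ys^2, "+"))
  phi2 <- 0.5 * (1 + tanh((r - radius) / width))
  phi2[r >= radius + 5 * width] <- 1
  domain_from_phi(rep(phi2, times = params$grid[3]), params,
                  radius = radius)
}
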