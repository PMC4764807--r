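test_that("phase field profile: tanh shape, bounds, monotonicity", {
  p <- test_params(grid = c(48, 48, 48))
  dom <- build_phase_field(p, radius = 2.5)
  expect_true(all(dom$phi >= 0 & dom$phi <= 1))
  ci <- round(dom$center / p$dx) + 1
  expect_lt(dom$phi[ci[1], ci[2], ci[3]], 0.01)
  # phi = 0.5 on the surface, saturated beyond 5 interface widths
  xs <- grid_coords(p, 1)
  mid <- dom$phi[, ci[2], ci[3]]
  r <- abs(xs - dom$center[1])
  expect_equal(stats::approx(r[xs >= dom$center[1]],
                             mid[xs >= dom$center[1]],
                             xout = dom$radius)$y, 0.5, tolerance = 0.02)
  expect_true(all(mid[r > dom$radius + 5 * dom$interface_width] == 1))
  # monotone non-decreasing in distance from the center along a ray
  ray <- mid[xs >= dom$center[1]]
  expect_true(all(diff(ray) >= -1e-12))
})

test_that("obstacles touching the outer boundary are rejected", {
  p <- test_params(grid = c(40, 40, 40))
  expect_error(build_phase_field(p, radius = 3.5), "margin")
  expect_error(build_phase_field(p, radius = 0.4), "radius")  # < 2 dx
  expect_silent(dom <- build_phase_field(p, radius = 2))
})

test_that("diffusion+forcing rate vanishes where it must", {
  p <- test_params(grid = c(30, 30, 30))
  dom <- build_phase_field(p, radius = 1.5)
  # uniform u, no field: all gradients vanish
  u <- array(0.3, dim = p$grid)
  r <- diffusion_and_forcing(u, dom, c(0, 0, 0), p)
  expect_lt(max(abs(r[dom$active == 1L])), 1e-12)
  # linear u in x, no obstacle: Laplacian of a linear field is zero
  # away from the no-flux outer boundary
  dom0 <- no_obstacle_domain(p)
  X <- array(rep(grid_coords(p, 1), times = prod(p$grid[2:3])),
             dim = p$grid)
  r <- diffusion_and_forcing(0.1 * X, dom0, c(0, 0, 0), p)
  interior <- r[2:23, 2:23, 2:23]
  expect_lt(max(abs(interior)), 1e-12)
})

test_that("discrete no-flux conservation: diffusion sums to zero", {
  p <- test_params(grid = c(24, 24, 24))
  dom0 <- no_obstacle_domain(p)
  u <- array(0, dim = p$grid)
  u[10:14, 10:14, 10:14] <- 0.8   # single bump
  r <- diffusion_and_forcing(u, dom0, c(0, 0, 0), p)
  # conservative flux form: the discrete integral of the diffusion rate
  # vanishes, so total u changes only through reaction terms
  expect_lt(abs(sum(r)) * p$dt, 1e-10)
})
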