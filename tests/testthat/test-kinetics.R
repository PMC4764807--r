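test_that("Barkley kinetics fixed points and pointwise rates", {
  p <- model_params()
  # rest state and excited state are exact fixed points
  expect_identical(barkley_reaction(0, 0, p), list(du = 0, dv = 0))
  r <- barkley_reaction(1, 1, p)
  expect_equal(r$du, 0)
  expect_equal(r$dv, 0)
  # direct evaluation: (1/0.02)*0.5*0.5*(0.5 - 0.18/0.9) = 3.75
  r <- barkley_reaction(0.5, 0.1, p)
  expect_equal(r$du, 3.75)
  expect_equal(r$dv, 0.4)
  # vectorized over arrays
  u <- array(c(0, 0.5, 1), dim = c(3, 1, 1))
  v <- array(c(0, 0.1, 1), dim = c(3, 1, 1))
  expect_equal(barkley_reaction(u, v, p)$du,
               array(c(0, 3.75, 0), dim = c(3, 1, 1)))
})

test_that("parameter validation enforces stability and positivity", {
  expect_error(model_params(a = -1), "a > 0")
  expect_error(model_params(dx = 0.25, dt = 0.2), "stability")
  p <- model_params(dx = 0.25)
  expect_lte(p$dt, 0.25^2 / 6)
  expect_equal(p$dt, 0.002)  # reaction-stiffness cap binds at dx = 0.25
  p2 <- model_params(dx = 0.1)
  expect_equal(p2$dt, 0.8 * 0.1^2 / 6)  # diffusion bound binds
})

test_that("single Euler step matches hand arithmetic on a uniform field", {
  p <- model_params(dx = 0.25, dt = 0.001, grid = c(8, 8, 8))
  dom <- no_obstacle_domain(p)
  u <- array(0.5, dim = p$grid)
  v <- array(0.1, dim = p$grid)
  st <- euler_step(medium_state(u, v), dom, field_spec("NONE"), p)
  # uniform field: diffusion contributes nothing; du = 3.75, dv = 0.4
  expect_equal(max(abs(st$u - 0.50375)), 0, tolerance = 1e-12)
  expect_equal(max(abs(st$v - 0.1004)), 0, tolerance = 1e-12)
  expect_equal(st$t, 0.001)
})

test_that("quiescent state is preserved exactly without a field", {
  p <- model_params(grid = c(16, 16, 16))
  dom <- build_phase_field(p, radius = 0.8)
  res <- integrate_medium(quiescent_state(p), dom, field_spec("NONE"), p,
                          t_end = 100, chunk = 20)
  expect_lt(max(abs(res$state$u)), 1e-12)
  expect_lt(max(abs(res$state$v)), 1e-12)
})

test_that("two half steps differ from one full step by O(dt^2)", {
  p1 <- model_params(grid = c(12, 12, 12), dt = 0.002)
  p2 <- model_params(grid = c(12, 12, 12), dt = 0.001)
  dom <- no_obstacle_domain(p1)
  set.seed(7)
  base <- 0.3 + 0.1 * sin(seq(0, pi, length.out = 12))
  u <- array(outer(outer(base, base), base), dim = p1$grid)
  v <- array(0.2, dim = p1$grid)
  st0 <- medium_state(u, v)
  f <- field_spec("NONE")
  one <- euler_step(st0, dom, f, p1)
  half <- euler_step(euler_step(st0, dom, f, p2), dom, f, p2)
  err <- max(abs(one$u - half$u))
  expect_gt(err, 0)
  # global first-order method: one-step difference is O(dt^2)
  expect_lt(err, 10 * p1$dt^2 * max(abs(barkley_reaction(u, v, p1)$du)))
})

test_that("instability errors name the first offending grid index", {
  p <- model_params(grid = c(8, 8, 8), dx = 0.25, dt = 0.002)
  dom <- no_obstacle_domain(p)
  u <- array(0, dim = p$grid)
  u[3, 4, 5] <- 1e308  # blows up immediately
  st <- medium_state(u, array(0, dim = p$grid))
  expect_error(euler_step(st, dom, field_spec("NONE"), p),
               "instability.*\\(.*[0-9].*\\).*t = ")
})
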