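test_that("quiescent state is all-zero and sized to the grid", {
  p <- test_params(grid = c(12, 14, 16))
  st <- quiescent_state(p)
  expect_equal(dim(st$u), c(12L, 14L, 16L))
  expect_true(all(st$u == 0) && all(st$v == 0))
  expect_equal(st$t, 0)
})

test_that("pinned scroll: filament attached, spans z, frequency stationary", {
  p <- study_params()
  dom <- study_domain(p)
  st <- cached_pinned()
  fil <- attr(st, "filament")
  expect_gt(nrow(fil), 20)
  dists <- sqrt(rowSums(sweep(fil, 2, dom$center)^2)) - dom$radius
  expect_lt(min(dists), 2 * p$dx)
  expect_gt(diff(range(fil[, 3])), 0.9 * (p$grid[3] - 1) * p$dx)
  # relaxation probes give a stationary rotation estimate
  omega <- attr(st, "omega_scroll")
  expect_true(is.finite(omega))
  probes <- attr(st, "probes")
  af <- activation_frequency(probes)
  iv <- af$intervals
  n <- length(iv)
  expect_gt(n, 3)
  # consecutive period estimates differ by < 2%
  expect_lt(max(abs(diff(iv))) / mean(iv), 0.02)
})

test_that("pinned-scroll construction is bitwise deterministic", {
  p <- model_params(grid = c(40, 40, 40))
  dom <- build_phase_field(p, radius = 1.5)
  s1 <- suppressWarnings(pinned_scroll_init(p, dom, relaxation_time = 6,
                                            verify = FALSE))
  s2 <- suppressWarnings(pinned_scroll_init(p, dom, relaxation_time = 6,
                                            verify = FALSE))
  expect_identical(s1$u, s2$u)
  expect_identical(s1$v, s2$v)
})

test_that("scroll ring: closed planar loop near the requested radius", {
  p <- study_params()
  st <- scroll_ring_init(p, ring_radius = 5, settle_time = 2)
  fil <- attr(st, "filament")
  ctr <- grid_center(p)
  expect_gt(nrow(fil), 50)
  rho <- sqrt((fil[, 1] - ctr[1])^2 + (fil[, 2] - ctr[2])^2)
  # loop circumference within 15% of the target
  expect_lt(abs(mean(rho) - 5) / 5, 0.15)
  # planar: z spread below one grid spacing
  expect_lt(stats::sd(fil[, 3]), p$dx)
  # closed loop: every point has a neighbor within 2 dx
  nn <- vapply(seq_len(nrow(fil)), function(i) {
    d <- sqrt(rowSums(sweep(fil[-i, , drop = FALSE], 2, fil[i, ])^2))
    min(d)
  }, numeric(1))
  expect_lt(max(nn), 2 * p$dx)
  # azimuthal coverage: gaps in angle below 20 degrees
  az <- sort(atan2(fil[, 2] - ctr[2], fil[, 1] - ctr[1]))
  gaps <- diff(c(az, az[1] + 2 * pi))
  expect_lt(max(gaps), 20 * pi / 180)
})

test_that("ring radius below the core size is rejected", {
  p <- test_params(grid = c(40, 40, 40))
  expect_error(scroll_ring_init(p, ring_radius = 2), "core size")
})
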