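test_that("filament detector: quiescent medium has no filament", {
  p <- test_params(grid = c(20, 20, 20))
  st <- quiescent_state(p)
  expect_equal(nrow(detect_filament(st, NULL, p)), 0)
})

test_that("filament detector recovers an analytic isosurface crossing", {
  p <- test_params(grid = c(20, 20, 20))
  x0 <- 2.3; y0 <- 3.1
  X <- array(rep(grid_coords(p, 1), times = prod(p$grid[2:3])),
             dim = p$grid)
  Y <- array(rep(rep(grid_coords(p, 2), each = p$grid[1]),
                 times = p$grid[3]), dim = p$grid)
  st <- medium_state(X - x0, Y - y0)
  pts <- detect_filament(st, NULL, p, u_iso = 0, v_iso = 0)
  # intersection of the planes x = x0 and y = y0: a vertical line
  expect_gt(nrow(pts), 10)
  expect_lt(max(abs(pts[, 1] - x0)), p$dx / 2)
  expect_lt(max(abs(pts[, 2] - y0)), p$dx / 2)
  # spans z
  expect_gt(diff(range(pts[, 3])), 0.8 * (p$grid[3] - 1) * p$dx)
})

test_that("removal classification from synthetic traces", {
  p <- test_params()
  dom <- build_phase_field(p, radius = 2)
  ctr <- dom$center
  zline <- seq(0, (p$grid[3] - 1) * p$dx, by = 0.5)
  # a transmural (z-spanning) filament line at surface distance d
  line <- function(d) cbind(ctr[1] + dom$radius + d, ctr[2], zline)
  times <- seq(0, 300, by = 10)
  pts <- lapply(times, function(t) {
    if (t >= 250) matrix(numeric(0), 0, 3)        # swept out of medium
    else line(0.02 * t * t / 10)                  # slow then fast
  })
  tr <- filament_trace(times, pts, dom, p)
  out <- classify_removal(tr, box_half_width = 2 * dom$radius,
                          t_limit = 500, dx = p$dx)
  expect_true(out$success)
  # leaves box when radius+d >= 4, d >= 2: 0.002 t^2 >= 2 at t ~ 31.6
  expect_equal(out$t_removed, 40)   # first sample time past the box
  # first sample with d > 2 dx = 0.5: 0.002 t^2 > 0.5 at t ~ 15.8
  expect_equal(out$t_detach, 20)
  # trace that never leaves the obstacle
  tr2 <- filament_trace(times, lapply(times, function(t) line(0)), dom, p)
  out2 <- classify_removal(tr2, t_limit = 500, dx = p$dx)
  expect_false(out2$success)
  expect_true(is.na(out2$t_detach))
  expect_true(is.na(out2$t_removed))
  # empty trace errors
  expect_error(classify_removal(filament_trace(numeric(0), list(), dom, p),
                                dx = p$dx), "empty")
})

test_that("short seams are not counted as reentrant filaments", {
  p <- test_params()
  dom <- build_phase_field(p, radius = 2)
  ctr <- dom$center
  # an arc of points spanning only a fifth of the box height
  arc <- cbind(ctr[1] + 3, ctr[2], ctr[3] + seq(-1, 1, by = 0.25))
  tr <- filament_trace(c(0, 10), list(arc, arc), dom, p)
  expect_equal(tr$n_spanning, c(0L, 0L))
  out <- classify_removal(tr, t_limit = 500, dx = p$dx)
  # no reentrant component anywhere: counts as removed at once
  expect_equal(out$t_removed, 0)
})

test_that("enlarging the box cannot decrease the removal time", {
  p <- test_params()
  dom <- build_phase_field(p, radius = 2)
  ctr <- dom$center
  zline <- seq(0, (p$grid[3] - 1) * p$dx, by = 0.5)
  times <- seq(0, 100, by = 5)
  pts <- lapply(times, function(t)
    cbind(ctr[1] + 2 + 0.05 * t, ctr[2], zline))
  tr <- filament_trace(times, pts, dom, p)
  t_small <- classify_removal(tr, box_half_width = 3, dx = p$dx)$t_removed
  t_big <- classify_removal(tr, box_half_width = 5, dx = p$dx)$t_removed
  expect_gte(t_big, t_small)
})

test_that("is_quiescent thresholds on tissue points", {
  p <- test_params(grid = c(16, 16, 16))
  dom <- build_phase_field(p, radius = 0.8)
  st <- quiescent_state(p)
  expect_true(is_quiescent(st, dom))
  st$u[2, 2, 2] <- 1
  expect_false(is_quiescent(st, dom))
})
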