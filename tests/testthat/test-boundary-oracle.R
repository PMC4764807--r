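# Sign-convention regression for the electric-field boundary coupling.
# (The quantitative slab/disk comparisons against the ghost-node and
# closed-form references run with the acceptance checks.)

test_that("static +x field depolarizes the +x obstacle face (3D)", {
  p <- model_params(grid = c(40, 40, 40))
  dom <- build_phase_field(p, radius = 2)
  st <- quiescent_state(p)
  # a few steps of pure forcing imprint the virtual-electrode pattern
  f <- field_spec("ACEF", E0 = 0.5, omega_e = 1e-3)  # quasi-static
  res <- integrate_medium(st, dom, f, p, t_end = 0.1)
  ctr <- round(dom$center / p$dx) + 1
  off <- round((dom$radius + 2 * dom$interface_width) / p$dx)
  u_plus <- res$state$u[ctr[1] + off, ctr[2], ctr[3]]
  u_minus <- res$state$u[ctr[1] - off, ctr[2], ctr[3]]
  expect_gt(u_plus, 0)
  expect_lt(u_minus, 0)
  # near-antisymmetric while the response is still small
  expect_equal(u_plus, -u_minus, tolerance = 0.1)
})
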