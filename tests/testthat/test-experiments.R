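# Cross-parameter robustness: the circularly polarized field's ability
# to out-pace the pinned scroll is not an artifact of the default
# kinetics.

test_that("alternative rigid-rotation kinetics: CP waves still beat the scroll", {
  p <- model_params(a = 0.8, b = 0.06, grid = c(60, 60, 60))
  dom <- build_phase_field(p, radius = 2.5)
  st <- pinned_scroll_init(p, dom, relaxation_time = 25)
  omega_scroll <- attr(st, "omega_scroll")
  expect_true(is.finite(omega_scroll))
  # drive 20% above the measured pinned frequency
  f <- field_spec("CPEF", 1.8, round(1.2 * omega_scroll, 2))
  r <- run_weh_quiescent(f, p, dom, t_end = 50)
  expect_true(r$emitted)
  expect_gt(r$omega_wave, omega_scroll)
})
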