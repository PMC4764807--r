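test_that("activation frequency of a synthetic periodic pulse train", {
  # period T = 2 within a gaussian-pulse train: omega = pi
  tt <- seq(0, 30, by = 0.01)
  pulse <- function(t) exp(-((t %% 2) - 0.5)^2 / 0.02)
  ser <- probe_series(matrix(0, 1, 3), tt, matrix(pulse(tt), ncol = 1))
  af <- activation_frequency(ser, threshold = 0.5)
  expect_equal(af$omega, pi, tolerance = 0.01 / 2)
  expect_lt(af$cv, 1e-6)
  # constant series: no activations
  flat <- probe_series(matrix(0, 1, 3), tt,
                       matrix(rep(0, length(tt)), ncol = 1))
  expect_error(activation_frequency(flat), "insufficient activations")
  # too few crossings after the transient discard
  short <- probe_series(matrix(0, 1, 3), tt[tt <= 10],
                        matrix(pulse(tt[tt <= 10]), ncol = 1))
  expect_error(activation_frequency(short), "insufficient activations")
})

test_that("crossing times are interpolated below the sampling interval", {
  tt <- seq(0, 40, by = 0.5)           # coarse sampling
  u <- sin(2 * pi * tt / 3.3)
  ser <- probe_series(matrix(0, 1, 3), tt, matrix(u, ncol = 1))
  af <- activation_frequency(ser, threshold = 0)
  expect_equal(af$omega, 2 * pi / 3.3, tolerance = 0.01)
})

test_that("probe series container validates uniform sampling", {
  expect_error(probe_series(matrix(0, 1, 3), c(0, 1, 1.5),
                            matrix(0, 3, 1)))
  expect_silent(probe_series(matrix(0, 1, 3), c(0, 1, 2),
                             matrix(0, 3, 1)))
})
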