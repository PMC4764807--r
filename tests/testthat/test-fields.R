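test_that("field_vector reproduces the three waveforms", {
  # circularly polarized: phase zero at t = 0, constant magnitude E0
  cp <- field_spec("CPEF", E0 = 1.8, omega_e = 3)
  expect_equal(field_vector(cp, 0)[1, ], c(x = 1.8, y = 0, z = 0))
  tt <- seq(0, 4, by = 0.05)
  expect_equal(unname(sqrt(rowSums(field_vector(cp, tt)^2))),
               rep(1.8, length(tt)))
  # AC along x: sign flips at half period
  ac <- field_spec("ACEF", E0 = 2, omega_e = 4)
  expect_equal(field_vector(ac, pi / 4)[1, ], c(x = -2, y = 0, z = 0))
  # pulsed DC: on for the first d of each period 2*pi/omega_e
  pd <- field_spec("PDCEF", E0 = 2, omega_e = 3.75, pulse_duration = 0.1)
  expect_equal(field_vector(pd, 0.05)[1, ], c(x = 2, y = 0, z = 0))
  expect_equal(field_vector(pd, 0.5)[1, ], c(x = 0, y = 0, z = 0))
  period <- 2 * pi / 3.75
  expect_equal(field_vector(pd, period + 0.02)[1, "x"], c(x = 2))
})

test_that("AC and CP fields average to zero over one period", {
  for (spec in list(field_spec("ACEF", 2, 3), field_spec("CPEF", 1.8, 3))) {
    period <- 2 * pi / spec$omega_e
    tt <- seq(0, period, length.out = 4001)[-1]
    avg <- colMeans(field_vector(spec, tt - period / 8000))
    expect_equal(unname(avg), c(0, 0, 0), tolerance = 1e-10)
  }
})

test_that("PDCEF duty cycle equals d * omega_e / (2 pi)", {
  spec <- field_spec("PDCEF", 2, 2.5, pulse_duration = 0.4)
  period <- 2 * pi / 2.5
  tt <- seq(0, period, length.out = 100001)[-1] - period / 200000
  frac <- mean(field_vector(spec, tt)[, "x"] != 0)
  expect_equal(frac, 0.4 / period, tolerance = 1e-3)
})

test_that("surface forcing follows n . E on the sphere", {
  cp <- field_spec("CPEF", E0 = 1.8, omega_e = 3)
  # poles: normal perpendicular to the rotation plane
  expect_equal(surface_forcing(cp, 0, 1.2, 0.7), 0, tolerance = 1e-12)
  # rotating maximum: n . E = E0 sin(theta) cos(az - omega t)
  expect_equal(surface_forcing(cp, pi / 2, 1.0, 2.0),
               1.8 * cos(1.0 - 3 * 2.0))
  ac <- field_spec("ACEF", E0 = 2, omega_e = 3)
  expect_equal(surface_forcing(ac, pi / 2, 0, 0), 2)
  pd <- field_spec("PDCEF", 2, 3.75, 0.1)
  expect_equal(surface_forcing(pd, pi / 2, pi / 2, 0.05), 0,
               tolerance = 1e-12)
})

test_that("forcing extrema: linear fields depend on azimuth, CP does not", {
  pd <- field_spec("PDCEF", 2, 3.75, 0.1)
  expect_equal(surface_forcing_extremum(pd, pi / 4, 0), 2 * sin(pi / 4))
  cp <- field_spec("CPEF", 2, 3)
  expect_equal(surface_forcing_extremum(cp, pi / 2, 0), 2)
  th <- seq(0, pi, length.out = 21)
  expect_equal(surface_forcing_extremum(cp, th, 0),
               surface_forcing_extremum(cp, th, 1.7))
  # numerical check of the CP extremum: maximize |n.E| over time
  th0 <- 1.1; az0 <- 0.6
  tt <- seq(0, 2 * pi / 3, length.out = 2000)
  num <- max(abs(surface_forcing(cp, th0, az0, tt)))
  expect_equal(num, surface_forcing_extremum(cp, th0, az0),
               tolerance = 1e-5)
})

test_that("CP extremum dominates the linear-field extremum everywhere", {
  th <- seq(0.01, pi - 0.01, length.out = 25)
  az <- seq(0, 2 * pi, length.out = 25)
  g <- expand.grid(th = th, az = az)
  ac <- field_spec("ACEF", 1.8, 3)
  cp <- field_spec("CPEF", 1.8, 3)
  expect_true(all(surface_forcing_extremum(cp, g$th, g$az) >=
                    surface_forcing_extremum(ac, g$th, g$az) - 1e-12))
})

test_that("field_spec validates its arguments", {
  expect_error(field_spec("PDCEF", 2, 3, pulse_duration = 3),
               "pulse_duration")
  expect_error(field_spec("CPEF", 2))
  expect_error(field_spec("ACEF", -1, 3))
  expect_equal(field_spec("NONE")$omega_e, 0)
  expect_equal(unname(field_vector(field_spec("NONE"), 1)[1, ]), c(0, 0, 0))
})
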