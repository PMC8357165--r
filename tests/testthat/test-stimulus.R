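# Pulse shapes, onset trains, and the spatial coupling of the stimulus.

test_that("pulse amplitudes invert the shape energy formulas", {
  # E = 40 a.u., D = 0.1 s
  expect_equal(pulse_amplitude("rectangular", 0.1, 40), 20.00, tolerance = 5e-4)
  expect_equal(pulse_amplitude("gaussian", 0.1, 40), 31.79, tolerance = 5e-4)
  for (sh in c("triangular", "rising_ramp", "decreasing_ramp"))
    expect_equal(pulse_amplitude(sh, 0.1, 40), 34.64, tolerance = 5e-4)
  # the trapezoid follows its energy formula, sqrt(3 E / (2 D))
  expect_equal(pulse_amplitude("rectangular_trapezoid", 0.1, 40), sqrt(600),
               tolerance = 1e-10)
  expect_error(pulse_spec("sawtooth"), "arg")
})

test_that("discrete pulse energy matches the analytic energy within 2%", {
  dt <- 1e-4
  for (sh in pulse_shapes()) {
    for (D in c(0.025, 0.05, 0.075, 0.1)) {
      u <- pulse_waveform(pulse_spec(sh, D, 40), dt)
      expect_equal(length(u), round(D / dt))
      e <- sum(u^2) * dt
      expect_gt(e, 0.98 * 40)
      expect_lt(e, 1.02 * 40)
    }
  }
})

test_that("the decreasing ramp is the exact time reversal of the rising ramp", {
  up <- pulse_waveform(pulse_spec("rising_ramp", 0.1, 40), 1e-4)
  down <- pulse_waveform(pulse_spec("decreasing_ramp", 0.1, 40), 1e-4)
  expect_identical(down, rev(up))
})

test_that("periodic onsets fill the active window on the stimulation period", {
  on <- generate_onsets("periodic", c(5, 905), rate = 0.85)
  expect_length(on, 766)  # onset at t = 5 plus floor(900 * 0.85) periods
  expect_equal(on[1], 5)
  expect_equal(diff(on), rep(1 / 0.85, 765))
  expect_length(generate_onsets("periodic", c(5, 5), rate = 0.85), 0)
  expect_length(generate_onsets("periodic", c(5, 4), rate = 0.85), 0)
})

test_that("poisson onsets have the requested mean and respect the refractory gap", {
  on <- generate_onsets("poisson", c(0, 1e4), lambda = 1 / 0.85,
                        min_sep = 0.1, seed = 42)
  gaps <- diff(on)
  expect_true(all(gaps >= 0.1 - 1e-9))
  expect_lt(abs(mean(gaps) - 1 / 0.85) / (1 / 0.85), 0.03)
  # determinism per seed
  expect_identical(on, generate_onsets("poisson", c(0, 1e4), lambda = 1 / 0.85,
                                       min_sep = 0.1, seed = 42))
  expect_false(identical(on[1], generate_onsets("poisson", c(0, 1e4),
                                                lambda = 1 / 0.85,
                                                min_sep = 0.1, seed = 43)[1]))
})

test_that("difference-of-Gaussians kernel follows the printed formula", {
  g <- grid_spec()
  w <- dog_kernel(g, center = c(7, 7), sigma_e = 1, sigma_i = 2)
  # centre value 1/(2 pi) - 1/(4 pi)
  centre <- 7 * 16 + 7 + 1
  expect_equal(w[centre], 1 / (2 * pi) - 1 / (4 * pi), tolerance = 1e-12)
  # direct formula evaluation on every node
  x <- rep(0:15, times = 16); y <- rep(0:15, each = 16)
  d2 <- (x - 7)^2 + (y - 7)^2
  expect_equal(w, exp(-d2 / 1) / (2 * pi) - exp(-d2 / 4) / (4 * pi),
               tolerance = 1e-12)
  # isotropy: swapping x and y about the centre leaves the kernel unchanged
  m <- matrix(w, 16, 16)
  expect_equal(m[1:16, 1:16], t(m)[1:16, 1:16])
  # identical widths cancel exactly
  expect_true(all(dog_kernel(g, sigma_e = 2, sigma_i = 2 + 1e-15) < 1e-12))
  expect_warning(dog_kernel(g, center = c(1, 7)), "boundary")
  expect_error(dog_kernel(g, center = c(20, 7)), "inside")
})

test_that("assembled input field has the stated noise power and pairing", {
  g <- grid_spec(); p <- nft_params()
  f <- assemble_input_field(g, p, duration = 0.05, seed = 5)  # 128000 draws
  expect_equal(mean(f), 1, tolerance = 0.02)
  expect_lt(abs(stats::var(as.vector(f)) - 9.67) / 9.67, 0.02)
  # same seed: noise component identical with and without stimulation
  pu <- pulse_spec("rectangular", 0.01, 1)
  f2 <- assemble_input_field(g, p, onsets = 0.02, pulse = pu,
                             duration = 0.05, seed = 5)
  u <- pulse_waveform(pu, g$dt)
  centre <- 7 * 16 + 7 + 1
  w0 <- (1 / (2 * pi) - 1 / (4 * pi))
  during <- 201:300  # steps covered by the pulse
  expect_equal(f2[centre, during] - f[centre, during],
               rep(w0 * u[1], 100), tolerance = 1e-9)
  expect_identical(f2[, 1:200], f[, 1:200])
  # zero-noise field carries exactly the mean plus the pulse
  p0 <- nft_params(noise_sd = 0)
  f3 <- assemble_input_field(g, p0, onsets = 0.02, pulse = pu,
                             duration = 0.05, seed = 1)
  expect_equal(unique(f3[centre, 1:200]), 1)
  expect_equal(f3[centre, 250], 1 + w0 * u[1], tolerance = 1e-12)
})
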