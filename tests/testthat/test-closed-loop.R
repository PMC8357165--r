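# The streaming phase estimator and the one-shot hysteresis trigger.

test_that("controller filters match the printed pole/zero layout", {
  ctrl <- design_controller(0.85, 0.01)
  # pole radii exactly as printed
  pn <- sort(Mod(polyroot(rev(ctrl$notch_a))))
  expect_equal(pn, c(0, 0.9999, 0.9999), tolerance = 1e-9)
  pq <- sort(Mod(polyroot(rev(ctrl$quad_a))))
  expect_equal(pq, c(0.999, 0.9999, 0.9999), tolerance = 1e-9)
  # notch zeros at z = 1 and z = -1: no DC or Nyquist gain
  zn <- sort(Re(polyroot(rev(ctrl$notch_b))))
  expect_equal(zn, c(-1, -1, 1), tolerance = 1e-9)
  expect_lt(Mod(controller_response(ctrl, 1e-9)$response), 1e-6)
  expect_error(design_controller(0.85, 1), "Nyquist")
})

test_that("notch selectivity at the stored rate exceeds 20 dB against 0.4 and 2 Hz", {
  ctrl <- design_controller(0.85, 0.01)
  g <- controller_response(ctrl, c(0.4, 0.85, 2))$gain_db
  expect_gt(g[2] - g[1], 20)
  expect_gt(g[2] - g[3], 20)
})

test_that("filter impulse responses decay to below 1e-6 of their peak", {
  ctrl <- design_controller(0.85, 1e-4)
  imp <- c(1, numeric(3e5 - 1))
  for (co in list(list(ctrl$notch_b, ctrl$notch_a),
                  list(ctrl$quad_b, ctrl$quad_a))) {
    h <- as.numeric(signal::filter(signal::Arma(b = co[[1]], a = co[[2]]), imp))
    expect_lt(max(abs(h[2.5e5:3e5])), 1e-6 * max(abs(h)))
  }
})

test_that("phase of a clean tone is tracked with small error after settling", {
  h <- 1e-4
  t <- seq(0, 40, by = h)
  x <- sin(2 * pi * 0.85 * t)
  ctrl <- design_controller(0.85, h)
  out <- controller_run(x, ctrl)
  sel <- t > 10
  err <- circular_diff(out$phase[sel], true_phase_deg(t[sel], 0.85))
  expect_lt(abs(circular_diff(circular_mean(err), 0)), 10)   # unbiased
  expect_lt(sqrt(mean(err^2)), 20)                           # bounded jitter
  # phase advances monotonically up to jitter: single-tick regressions are
  # rare and the unwrapped phase always advances over 0.2 s spans
  dph <- circular_diff(out$phase[sel][-1], out$phase[sel][-sum(sel)])
  expect_gt(mean(dph > -1e-6), 0.85)
  unwrapped <- cumsum(c(0, dph))
  lag <- 2000
  expect_true(all(diff(unwrapped, lag = lag) > 0))
  expect_equal(mean(dph), 360 * 0.85 * h, tolerance = 0.02)
})

test_that("envelope follows the rectified peaks and normalisation is scale-free", {
  h <- 1e-4
  t <- seq(0, 30, by = h)
  x <- sin(2 * pi * 0.85 * t)
  ctrl <- design_controller(0.85, h)
  out1 <- controller_run(x, ctrl)
  out2 <- controller_run(100 * x, ctrl)
  sel <- t > 10
  expect_gt(min(out1$envelope[sel]), 0)
  expect_equal(out2$envelope[sel] / out1$envelope[sel],
               rep(100, sum(sel)), tolerance = 1e-6)
  expect_equal(out1$phase, out2$phase, tolerance = 1e-6)
  # an all-zero input never fires
  out0 <- controller_run(numeric(1e4), ctrl)
  expect_false(any(out0$fire))
})

test_that("the trigger is one-shot per cycle with hysteresis re-arming", {
  h <- 1e-4
  t <- seq(0, 60, by = h)
  x <- sin(2 * pi * 0.85 * t)
  for (tgt in c(0, 90)) {
    ctrl <- design_controller(0.85, h, target_phase = tgt)
    out <- controller_run(x, ctrl)
    fires <- which(out$fire & t > 10)
    # about one fire per period of f0, never more
    n_per <- length(fires) / ((max(t) - 10) * 0.85)
    expect_lte(n_per, 1 + 1e-6)
    expect_gt(n_per, 0.9)
    expect_gte(min(diff(t[fires])), 0.5 / 0.85)
    # fires land inside the hysteresis window around the target
    err <- circular_diff(true_phase_deg(t[fires], 0.85), tgt)
    expect_lt(abs(circular_diff(circular_mean(err), 0)), 25)
  }
})

test_that("closed-loop runs are deterministic and silent without oscillation", {
  p <- default_params
  pr <- stim_protocol("closed_loop", pulse_spec("decreasing_ramp", 0.1, 40),
                      target_phase = 0)
  a <- cached_sim("cl_det_a",
                  simulate_nft(p, default_grid, pr, duration = 20, seed = 5))
  b <- simulate_nft(p, default_grid, pr, duration = 20, seed = 5)
  expect_identical(a$stim_onsets, b$stim_onsets)
  expect_identical(a$trace$x, b$trace$x)
  expect_gt(length(a$stim_onsets), 0)
  # flat trace (no noise, at the fixed point) never reaches the target phase
  p0 <- nft_params(noise_sd = 0)
  s0 <- simulate_nft(p0, default_grid, pr, duration = 15, seed = 1,
                     init = "steady")
  expect_length(s0$stim_onsets, 0)
})

test_that("offline phase reference is consistent with a known sinusoid", {
  rate <- 100
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * 0.85 * t)
  ph <- offline_phase(x, rate)
  sel <- t > 10 & t < 50
  err <- circular_diff(ph[sel], true_phase_deg(t[sel], 0.85))
  expect_lt(abs(circular_diff(circular_mean(err), 0)), 3)
  expect_lt(sqrt(mean(err^2)), 5)
})
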